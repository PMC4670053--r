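#' SVM configuration
#'
#' Hyperparameters for the binary RBF-kernel support vector machine. The
#' tuning grid spans `10^k` for integer exponents `grid_exponents` in both
#' gamma and cost — the default −10…10 gives 441 candidate pairs, a decade-
#' step reading of tuning "for a large range of values".
#'
#' @param gamma RBF kernel width (> 0), or `NULL` before tuning.
#' @param cost regularization parameter C (> 0), or `NULL` before tuning.
#' @param grid_exponents integer exponents for the tuning grid.
#' @param class_weighting `"balanced"` scales each class's C by
#'   `n / (2 n_k)` (field annotations are imbalanced: far more class-0
#'   candidates than songs); `"none"` uses the same C for both classes.
#' @param tuning_mode `"cv"` (default) scores each grid pair by mean balanced
#'   accuracy over 5-fold stratified cross-validation; `"paper"` scores by
#'   balanced accuracy of train-on-all/predict-all, reproducing the original
#'   procedure (which leaks information, hence not the default).
#' @param standardize z-score features with training-set statistics before
#'   fitting (recommended: the RBF kernel is distance-based).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(gamma = NULL, cost = NULL, grid_exponents = -10:10,
                       class_weighting = c("balanced", "none"),
                       tuning_mode = c("cv", "paper"), standardize = TRUE) {
  class_weighting <- match.arg(class_weighting)
  tuning_mode <- match.arg(tuning_mode)
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive")
  if (!is.null(cost) && cost <= 0) stop("cost must be positive")
  if (length(grid_exponents) == 0L) stop("tuning grid must be nonempty")
  structure(list(gamma = gamma, cost = cost,
                 grid_exponents = as.integer(grid_exponents),
                 class_weighting = class_weighting,
                 tuning_mode = tuning_mode, standardize = standardize),
            class = "svm_config")
}

# Coerce labels to a factor with levels c("absence", "presence").
as_binary_labels <- function(labels) {
  if (is.logical(labels))
    labels <- ifelse(labels, "presence", "absence")
  f <- factor(as.character(labels), levels = c("absence", "presence"))
  if (any(is.na(f))) stop("labels must be 'presence'/'absence' (or logical)")
  f
}

check_features <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) stop("features must have column names")
  bad <- which(rowSums(!is.finite(x)) > 0L)
  if (length(bad) > 0L)
    stop("non-finite feature value(s) in row ", bad[1L])
  x
}

#' Train the binary RBF-SVM
#'
#' Features are z-score standardized with training-set statistics (zero-
#' variance features are dropped and recorded), then a soft-margin SVM with
#' radial basis kernel is fitted by sequential minimal optimization.
#' Deterministic given inputs.
#'
#' @param features numeric matrix/data frame with named columns.
#' @param labels presence/absence labels (factor, character or logical).
#' @param cfg an [svm_config()] with `gamma` and `cost` set.
#' @return Object of class `trained_classifier` holding the support vectors
#'   (standardized), dual coefficients, intercept, feature schema,
#'   standardization parameters and the configuration.
#' @export
train_classifier <- function(features, labels, cfg) {
  stopifnot(inherits(cfg, "svm_config"))
  if (is.null(cfg$gamma) || is.null(cfg$cost))
    stop("svm_config must have gamma and cost set (run tune_hyperparameters)")
  X <- check_features(features)
  y <- as_binary_labels(labels)
  if (length(y) != nrow(X)) stop("features and labels length mismatch")
  tab <- table(y)
  if (any(tab < 2L)) stop("need at least 2 training examples in each class")

  mu <- colMeans(X)
  # population sd: standardization is then invariant to duplicating rows
  sdev <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  dropped <- character(0)
  if (cfg$standardize) {
    keep <- sdev > 1e-12
    dropped <- colnames(X)[!keep]
    X <- X[, keep, drop = FALSE]
    mu <- mu[keep]; sdev <- sdev[keep]
    if (ncol(X) == 0L) stop("all features have zero variance")
    Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, `/`)
  } else {
    mu <- rep(0, ncol(X)); sdev <- rep(1, ncol(X))
    names(mu) <- names(sdev) <- colnames(X)
    Xs <- X
  }

  yv <- ifelse(y == "presence", 1, -1)
  n <- nrow(Xs)
  Cvec <- if (cfg$class_weighting == "balanced") {
    w <- n / (2 * tab)
    cfg$cost * as.numeric(w[as.character(y)])
  } else rep(cfg$cost, n)

  fit <- .smo_fit(Xs, yv, cfg$gamma, Cvec, 1e-3,
                  as.integer(min(2e7, 50 * n + 20000)))
  sv <- which(fit$alpha > 1e-12)
  structure(list(support_vectors = Xs[sv, , drop = FALSE],
                 coef = fit$alpha[sv] * yv[sv], rho = fit$rho,
                 schema = colnames(Xs), mean = mu, sd = sdev,
                 dropped = dropped, config = cfg,
                 levels = c("absence", "presence"),
                 n_train = n, converged = fit$converged),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier: %d SVs / %d rows, gamma=%g, cost=%g>\n",
              nrow(x$support_vectors), x$n_train,
              x$config$gamma, x$config$cost))
  invisible(x)
}

# Schema-aligned, standardized matrix for prediction.
align_features <- function(model, features) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) stop("features must have column names")
  missing <- setdiff(model$schema, colnames(X))
  if (length(missing) > 0L)
    stop("schema mismatch: missing feature column(s): ",
         paste(missing, collapse = ", "))
  X <- X[, model$schema, drop = FALSE]
  sweep(sweep(X, 2L, model$mean), 2L, model$sd, `/`)
}

#' Signed decision scores
#'
#' `f(x) = sum_i coef_i K(sv_i, x) - rho`; positive scores mean presence.
#' Scores are signed distances to the decision boundary (up to the margin
#' scale) and feed the ROC analysis.
#'
#' @param model a [train_classifier()] result.
#' @param features feature matrix/data frame with named columns matching the
#'   model schema (extra columns are ignored; column order is irrelevant).
#' @return Numeric vector of scores.
#' @export
decision_scores <- function(model, features) {
  stopifnot(inherits(model, "trained_classifier"))
  Xs <- align_features(model, features)
  sv <- model$support_vectors
  d2 <- outer(rowSums(Xs^2), rowSums(sv^2), `+`) - 2 * tcrossprod(Xs, sv)
  d2[d2 < 0] <- 0
  as.numeric(exp(-model$config$gamma * d2) %*% model$coef) - model$rho
}

#' Predict presence/absence
#'
#' @param object a [train_classifier()] result.
#' @param newdata feature matrix/data frame.
#' @param ... unused.
#' @return Factor with levels `c("absence", "presence")`; presence where the
#'   decision score exceeds zero.
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  s <- decision_scores(object, newdata)
  factor(ifelse(s > 0, "presence", "absence"),
         levels = c("absence", "presence"))
}

#' Tune (gamma, cost) over a decade grid
#'
#' Evaluates every pair `10^i x 10^j` over `cfg$grid_exponents` by balanced
#' accuracy: in `"cv"` mode the mean over 5-fold stratified cross-validation
#' (folds fixed by `seed`, shared by all pairs); in `"paper"` mode the BAC of
#' training on all data and predicting the same data. Ties break toward
#' smaller cost, then smaller gamma.
#'
#' @param features,labels as in [train_classifier()].
#' @param cfg an [svm_config()].
#' @param seed integer seed for the cross-validation folds.
#' @return `cfg` with `gamma` and `cost` filled in; attribute `bac` holds the
#'   winning criterion value and `grid` the scored surface (in cv mode,
#'   pairs abandoned by an exact branch-and-bound — provably unable to beat
#'   the winner — are recorded as `-Inf`).
#' @export
tune_hyperparameters <- function(features, labels, cfg = svm_config(),
                                 seed = 1L) {
  stopifnot(inherits(cfg, "svm_config"))
  X <- check_features(features)
  y <- as_binary_labels(labels)
  if (nlevels(droplevels(y)) < 2L) stop("labels contain a single class")
  if (any(table(y) < 2L)) stop("need at least 2 examples per class")

  grid <- expand.grid(gamma = 10^cfg$grid_exponents,
                      cost = 10^cfg$grid_exponents)
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]

  folds <- NULL
  if (cfg$tuning_mode == "cv") {
    k <- min(5L, min(table(y)))
    folds <- with_seed(seed, {
      f <- integer(length(y))
      for (cl in levels(y)) {
        ii <- which(y == cl)
        f[ii] <- sample(rep_len(seq_len(k), length(ii)))
      }
      f
    })
  }

  # Score one pair. In cv mode, `floor` enables an exact branch-and-bound:
  # folds are evaluated sequentially and the pair is abandoned as soon as
  # even perfect (BAC 100) remaining folds could not beat `floor` — the
  # returned -Inf can never be the argmax, so the selection (including its
  # tie-breaks) is identical to exhaustive evaluation.
  score_pair <- function(gamma, cost, bound = -Inf) {
    cfg_i <- cfg; cfg_i$gamma <- gamma; cfg_i$cost <- cost
    if (cfg$tuning_mode == "paper") {
      m <- train_classifier(X, y, cfg_i)
      return(balanced_accuracy(predict(m, X), y)$bac)
    }
    K <- max(folds)
    tot <- 0
    for (f in seq_len(K)) {
      tr <- folds != f
      m <- train_classifier(X[tr, , drop = FALSE], y[tr], cfg_i)
      tot <- tot + balanced_accuracy(predict(m, X[!tr, , drop = FALSE]),
                                     y[!tr])$bac
      if ((tot + (K - f) * 100) / K < bound) return(-Inf)
    }
    tot / K
  }

  best_bac <- -Inf; best_i <- NA_integer_
  surface <- rep(NA_real_, nrow(grid))
  # probe a central pair first so the branch-and-bound floor is high early;
  # its result is recorded and the pair skipped in the ordered pass
  probe <- which(grid$gamma == 1 & grid$cost == 1)
  order_idx <- c(probe, setdiff(seq_len(nrow(grid)), probe))
  for (i in order_idx) {
    b <- tryCatch(score_pair(grid$gamma[i], grid$cost[i], bound = best_bac),
                  error = function(e) -Inf)
    surface[i] <- b
    if (b > best_bac || (b == best_bac && !is.na(best_i) && i < best_i)) {
      best_bac <- b; best_i <- i
    }
  }
  if (!is.finite(best_bac)) stop("tuning failed on every grid point")
  out <- cfg
  out$gamma <- grid$gamma[best_i]
  out$cost <- grid$cost[best_i]
  attr(out, "bac") <- best_bac
  attr(out, "grid") <- cbind(grid, bac = surface)
  out
}

.model_version <- "songsvm-model-1"

#' Save / load a trained classifier
#'
#' The model file is a single JSON artifact (full-precision doubles) holding
#' the feature schema, standardization parameters, SVM state and
#' configuration; a load reproduces predictions bit-identically.
#'
#' @param model a `trained_classifier`.
#' @param path file path (`.json`).
#' @return `save_model`: `path` invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_classifier"))
  obj <- list(version = .model_version,
              schema = model$schema, mean = model$mean, sd = model$sd,
              dropped = model$dropped,
              support_vectors = model$support_vectors,
              coef = model$coef, rho = model$rho,
              gamma = model$config$gamma, cost = model$config$cost,
              class_weighting = model$config$class_weighting,
              tuning_mode = model$config$tuning_mode,
              standardize = model$config$standardize,
              n_train = model$n_train, converged = model$converged)
  # I(17) significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("I/O error: cannot parse model file: ",
                         conditionMessage(e)))
  if (!identical(obj$version, .model_version))
    stop("version mismatch: expected ", .model_version)
  sv <- matrix(as.numeric(obj$support_vectors),
               ncol = length(obj$schema),
               dimnames = list(NULL, obj$schema))
  cfg <- svm_config(gamma = obj$gamma, cost = obj$cost,
                    class_weighting = obj$class_weighting,
                    tuning_mode = obj$tuning_mode,
                    standardize = obj$standardize)
  structure(list(support_vectors = sv, coef = as.numeric(obj$coef),
                 rho = obj$rho, schema = obj$schema,
                 mean = stats::setNames(as.numeric(obj$mean), obj$schema),
                 sd = stats::setNames(as.numeric(obj$sd), obj$schema),
                 dropped = as.character(obj$dropped %||% character(0)),
                 config = cfg, levels = c("absence", "presence"),
                 n_train = obj$n_train, converged = obj$converged),
            class = "trained_classifier")
}
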