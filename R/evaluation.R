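#' Balanced accuracy
#'
#' `BAC = (P(A) + P(B)) / 2 x 100`, where `P(A)` is the proportion of
#' presence selections correctly classified and `P(B)` the proportion of
#' absence selections correctly classified. Robust to class imbalance; equals
#' ordinary accuracy on perfectly balanced truth.
#'
#' @param pred,truth presence/absence labels (factor, character or logical)
#'   of equal length; `truth` must contain both classes.
#' @return List with `bac` (percent), `p_a`, `p_b`.
#' @export
balanced_accuracy <- function(pred, truth) {
  pred <- as_binary_labels(pred)
  truth <- as_binary_labels(truth)
  if (length(pred) != length(truth)) stop("pred and truth length mismatch")
  if (nlevels(droplevels(truth)) < 2L)
    stop("truth contains a single class: P(A)/P(B) undefined")
  p_a <- mean(pred[truth == "presence"] == "presence")
  p_b <- mean(pred[truth == "absence"] == "absence")
  list(bac = (p_a + p_b) / 2 * 100, p_a = p_a, p_b = p_b)
}

#' Area under the ROC curve
#'
#' Mann–Whitney formulation: the probability that a random presence example
#' scores above a random absence example, with ties counted one-half.
#'
#' @param scores numeric decision scores (higher = more presence-like).
#' @param truth presence/absence labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as_binary_labels(truth)
  if (length(scores) != length(truth)) stop("scores and truth length mismatch")
  if (nlevels(droplevels(truth)) < 2L)
    stop("truth contains a single class: AUC undefined")
  pos <- truth == "presence"
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified holdout evaluation
#'
#' Per repetition: stratified random split into a training fraction (default
#' 70%) and a validation remainder (30%); the SVM is trained on the training
#' rows only and balanced accuracy / AUC are computed on the held-out rows.
#' Reports mean and SD over repetitions. Each repetition uses a sub-seed
#' derived from (`seed`, rep), so increasing `n_reps` never reshuffles
#' earlier repetitions.
#'
#' @param features,labels as in [train_classifier()].
#' @param cfg an [svm_config()] with `gamma`/`cost` set.
#' @param classes optional integer vector of 0–3 annotation classes aligned
#'   with rows, for the per-class accuracy diagnostic.
#' @param train_fraction fraction of rows used for training (default 0.7).
#' @param n_reps number of repetitions (default 1000).
#' @param seed integer seed.
#' @return Object of class `evaluation_result`: `bac_mean`, `bac_sd`, `p_a`,
#'   `p_b`, `auc`, `n_reps`, `train_fraction`, `seed`, `per_class_accuracy`.
#' @export
repeated_holdout <- function(features, labels, cfg, classes = NULL,
                             train_fraction = 0.7, n_reps = 1000L,
                             seed = 1L) {
  X <- check_features(features)
  y <- as_binary_labels(labels)
  if (any(table(y) < 2L))
    stop("a class is too small to stratify the split")
  if (!is.null(classes) && length(classes) != length(y))
    stop("classes must align with labels")

  bac <- p_a <- p_b <- auc <- numeric(n_reps)
  cls_levels <- if (!is.null(classes)) sort(unique(classes)) else integer(0)
  cls_sum <- stats::setNames(numeric(length(cls_levels)),
                             as.character(cls_levels))
  cls_n <- cls_sum
  for (r in seq_len(n_reps)) {
    tr <- with_seed(derive_seed(seed, r),
                    stratified_train_idx(y, train_fraction))
    va <- setdiff(seq_along(y), tr)
    m <- train_classifier(X[tr, , drop = FALSE], y[tr], cfg)
    sc <- decision_scores(m, X[va, , drop = FALSE])
    pred <- factor(ifelse(sc > 0, "presence", "absence"),
                   levels = c("absence", "presence"))
    b <- balanced_accuracy(pred, y[va])
    bac[r] <- b$bac; p_a[r] <- b$p_a; p_b[r] <- b$p_b
    auc[r] <- roc_auc(sc, y[va])
    if (!is.null(classes)) {
      correct <- ifelse(classes[va] == 0L, pred == "absence",
                        pred == "presence")
      for (cl in cls_levels) {
        ii <- classes[va] == cl
        if (any(ii)) {
          key <- as.character(cl)
          cls_sum[key] <- cls_sum[key] + mean(correct[ii])
          cls_n[key] <- cls_n[key] + 1
        }
      }
    }
  }
  structure(list(bac_mean = mean(bac), bac_sd = stats::sd(bac),
                 p_a = mean(p_a), p_b = mean(p_b), auc = mean(auc),
                 n_reps = as.integer(n_reps),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 per_class_accuracy = if (length(cls_levels) > 0L)
                   cls_sum / pmax(cls_n, 1) else NULL),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("BAC %.2f (SD %.2f)  P(A) %.3f  P(B) %.3f  AUC %.3f  [%d reps, %.0f%% train]\n",
              x$bac_mean, x$bac_sd, x$p_a, x$p_b, x$auc, x$n_reps,
              100 * x$train_fraction))
  invisible(x)
}

#' Learning curve over training-data fractions
#'
#' For each fraction, each of the `n_reps` repetitions draws a *fresh*
#' stratified subsample (without replacement) of that fraction of the data,
#' splits it 70/30, trains and evaluates — so the reported SD includes the
#' subset-draw variability, matching the published procedure ("randomly
#' selecting a proportion of the training data and recalculating the BAC,
#' repeated 100 times"). The default fractions are 90% down to 10% in steps
#' of 10; fraction 1 reproduces [repeated_holdout()] on the full data
#' exactly (same seed).
#'
#' @inheritParams repeated_holdout
#' @param fractions data fractions in `(0, 1]`.
#' @param n_reps repetitions per fraction (default 100).
#' @return `data.frame` with `fraction`, `bac_mean`, `bac_sd`, `n_reps`, `n`
#'   (rows available at that fraction).
#' @export
learning_curve <- function(features, labels, cfg,
                           fractions = seq(0.9, 0.1, by = -0.1),
                           n_reps = 100L, train_fraction = 0.7, seed = 1L) {
  X <- check_features(features)
  y <- as_binary_labels(labels)
  if (any(!is.finite(fractions)) || any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    if (f >= 1) {
      res <- repeated_holdout(X, y, cfg, train_fraction = train_fraction,
                              n_reps = n_reps, seed = seed)
      return(data.frame(fraction = f, bac_mean = res$bac_mean,
                        bac_sd = res$bac_sd, n_reps = as.integer(n_reps),
                        n = length(y)))
    }
    bacs <- vapply(seq_len(n_reps), function(r) {
      with_seed(derive_seed(seed, i * 131071L + r), {
        idx <- stratified_train_idx(y, f)
        if (any(table(y[idx]) < 2L))
          stop("fraction ", f, " leaves fewer than 2 rows in a class")
        tr <- idx[stratified_train_idx(y[idx], train_fraction)]
        va <- setdiff(idx, tr)
        m <- train_classifier(X[tr, , drop = FALSE], y[tr], cfg)
        balanced_accuracy(predict(m, X[va, , drop = FALSE]), y[va])$bac
      })
    }, numeric(1))
    data.frame(fraction = f, bac_mean = mean(bacs), bac_sd = stats::sd(bacs),
               n_reps = as.integer(n_reps), n = round(f * length(y)))
  })
  do.call(rbind, rows)
}

#' Match detections against ground truth
#'
#' Greedy one-to-one matching by descending temporal-overlap fraction
#' (intersection divided by truth duration); a pair matches when that
#' fraction reaches `overlap_threshold`.
#'
#' @param detected,truth selection data frames for the same recording.
#' @param overlap_threshold minimum intersection/truth-duration (default 0.5).
#' @return Object of class `detector_score`: `recall`, `precision`,
#'   `n_truth`, `n_detected`, `n_matched`, `overlap_threshold`,
#'   `precision_defined` (FALSE when there were no detections) and `pairs`
#'   (matched index pairs with the truth's class label when present).
#' @export
match_detections <- function(detected, truth, overlap_threshold = 0.5) {
  n_d <- nrow(detected); n_t <- nrow(truth)
  pairs <- data.frame(det = integer(0), truth = integer(0),
                      overlap = numeric(0))
  if (n_d > 0L && n_t > 0L) {
    inter <- outer(detected$end_time, truth$end_time, pmin) -
             outer(detected$begin_time, truth$begin_time, pmax)
    inter[inter < 0] <- 0
    frac <- sweep(inter, 2L, truth$end_time - truth$begin_time, `/`)
    cand <- which(frac >= overlap_threshold, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      ov <- frac[cand]
      ord <- order(-ov, cand[, 2L], cand[, 1L])  # deterministic tie-break
      used_d <- logical(n_d); used_t <- logical(n_t)
      keep <- list()
      for (k in ord) {
        d <- cand[k, 1L]; t <- cand[k, 2L]
        if (!used_d[d] && !used_t[t]) {
          used_d[d] <- TRUE; used_t[t] <- TRUE
          keep[[length(keep) + 1L]] <- data.frame(det = d, truth = t,
                                                  overlap = frac[d, t])
        }
      }
      if (length(keep) > 0L) pairs <- do.call(rbind, keep)
    }
  }
  if (!is.null(truth$class_label) && nrow(pairs) > 0L)
    pairs$class_label <- truth$class_label[pairs$truth]
  n_m <- nrow(pairs)
  structure(list(recall = if (n_t > 0L) n_m / n_t else NA_real_,
                 precision = if (n_d > 0L) n_m / n_d else 0,
                 precision_defined = n_d > 0L,
                 n_truth = n_t, n_detected = n_d, n_matched = n_m,
                 overlap_threshold = overlap_threshold, pairs = pairs),
            class = "detector_score")
}

#' @export
print.detector_score <- function(x, ...) {
  cat(sprintf("recall %.3f  precision %.3f  (%d/%d truth matched, %d detected)\n",
              x$recall, x$precision, x$n_matched, x$n_truth, x$n_detected))
  invisible(x)
}
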