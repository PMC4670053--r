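test_that("training on separable blobs reaches BAC 100", {
  b <- make_blobs(100, sep = 4, seed = 2)
  cfg <- svm_config(gamma = 0.5, cost = 1)
  m <- train_classifier(b$X, b$y, cfg)
  expect_equal(balanced_accuracy(predict(m, b$X), b$y)$bac, 100)

  # duplicating every row leaves predictions unchanged
  m2 <- train_classifier(rbind(b$X, b$X), c(b$y, b$y), cfg)
  expect_equal(predict(m2, b$X), predict(m, b$X))

  expect_error(train_classifier(b$X[1:100, ], b$y[1:100], cfg),
               "each class")
  bad <- b$X; bad[3, 1] <- NA
  expect_error(train_classifier(bad, b$y, cfg), "row 3")
})

test_that("decision function matches an independent reference", {
  # fixture: 40+40 overlapping Gaussians, gamma 0.5, C 2, no weighting, no
  # standardization; expected values computed with scikit-learn's SVC
  # (libsvm) on identical data
  set.seed(42)
  X <- rbind(matrix(rnorm(80, 0, 1.5), ncol = 2),
             matrix(rnorm(80, 1.5, 1.5), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("absence", "presence"), each = 40)
  m <- train_classifier(X, y, svm_config(gamma = 0.5, cost = 2,
                                         class_weighting = "none",
                                         standardize = FALSE))
  grid <- as.matrix(expand.grid(f1 = c(-2, -1, 0, 1, 2, 3),
                                f2 = c(-1, 0.5, 2)))
  ref <- c(-0.641413, -1.021315, -1.428645, -0.116624, 0.171692, -0.910064,
           -0.815546, -1.099265, -0.528030, 1.008717, 0.787434, 1.167851,
           -1.142167, -1.084165, -0.335295, 0.879953, 0.966027, 1.158802)
  expect_equal(decision_scores(m, grid), ref, tolerance = 0.02)
})

test_that("predictions are schema-keyed and threshold the scores at zero", {
  b <- make_blobs(40, sep = 3, seed = 5, p = 3)
  m <- train_classifier(b$X, b$y, svm_config(gamma = 0.2, cost = 10))
  s <- decision_scores(m, b$X)
  expect_equal(predict(m, b$X) == "presence", s > 0, ignore_attr = TRUE)

  perm <- b$X[, c(3, 1, 2)]
  expect_equal(predict(m, perm), predict(m, b$X))
  expect_error(decision_scores(m, b$X[, 1:2]), "missing feature column")
})

test_that("zero-variance features are dropped and recorded", {
  b <- make_blobs(30, sep = 4, seed = 6)
  X <- cbind(b$X, dead = rep(1, nrow(b$X)))
  m <- train_classifier(X, b$y, svm_config(gamma = 0.5, cost = 1))
  expect_identical(m$dropped, "dead")
  expect_false("dead" %in% m$schema)
  expect_equal(balanced_accuracy(predict(m, X), b$y)$bac, 100)
})

test_that("tuning selects a working pair with stated tie-breaks", {
  b <- make_blobs(30, sep = 6, seed = 7)
  one <- svm_config(grid_exponents = 0L)  # grid of a single pair
  got <- tune_hyperparameters(b$X, b$y, one)
  expect_equal(c(got$gamma, got$cost), c(1, 1))

  cfg <- svm_config(grid_exponents = -2:2, tuning_mode = "paper")
  tuned <- tune_hyperparameters(b$X, b$y, cfg)
  expect_equal(attr(tuned, "bac"), 100)
  # best-BAC invariant over the whole surface
  surf <- attr(tuned, "grid")
  expect_true(all(attr(tuned, "bac") >= surf$bac))
  # ties break toward smaller cost then smaller gamma
  winners <- surf[surf$bac == max(surf$bac), ]
  winners <- winners[order(winners$cost, winners$gamma), ]
  expect_equal(c(tuned$gamma, tuned$cost),
               c(winners$gamma[1], winners$cost[1]))

  expect_error(tune_hyperparameters(b$X, rep("presence", nrow(b$X)),
                                    cfg), "single class")
})

test_that("default grid spans 10^-10..10^10 in decade steps (441 pairs)", {
  cfg <- svm_config()
  expect_equal(cfg$grid_exponents, -10:10)
  grid <- expand.grid(gamma = 10^cfg$grid_exponents,
                      cost = 10^cfg$grid_exponents)
  expect_equal(nrow(grid), 441L)
  expect_equal(range(grid$gamma), c(1e-10, 1e10))
})

test_that("model files round trip bit-identically", {
  b <- make_blobs(25, sep = 2, seed = 8, p = 4)
  m <- train_classifier(b$X, b$y, svm_config(gamma = 0.3, cost = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  set.seed(9)
  Xnew <- matrix(rnorm(200), ncol = 4,
                 dimnames = list(NULL, colnames(b$X)))
  expect_identical(decision_scores(m2, Xnew), decision_scores(m, Xnew))
  expect_identical(predict(m2, Xnew), predict(m, Xnew))
  expect_equal(m2$config$gamma, 0.3)
  expect_equal(m2$config$cost, 5)

  # truncated file errors
  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), path)
  expect_error(load_model(path), "model file")
})
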