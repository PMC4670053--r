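test_that("balanced accuracy follows its definition", {
  truth <- rep(c("presence", "absence"), each = 10)
  expect_equal(balanced_accuracy(truth, truth)$bac, 100)

  # P(A) = 0.9, P(B) = 0.8 -> 85
  pred <- truth
  pred[1] <- "absence"          # 9/10 presence correct
  pred[11:12] <- "presence"     # 8/10 absence correct
  b <- balanced_accuracy(pred, truth)
  expect_equal(b$bac, 85)
  expect_equal(b$p_a, 0.9)
  expect_equal(b$p_b, 0.8)

  # all-presence on balanced truth -> 50
  expect_equal(balanced_accuracy(rep("presence", 20), truth)$bac, 50)
  expect_error(balanced_accuracy(pred, rep("presence", 20)), "single class")

  # equals plain accuracy on balanced truth
  set.seed(1)
  pred2 <- sample(c("presence", "absence"), 20, replace = TRUE)
  expect_equal(balanced_accuracy(pred2, truth)$bac, 100 * mean(pred2 == truth))
})

test_that("roc_auc matches hand-computable cases", {
  truth <- c("presence", "absence", "presence", "absence")
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), truth), 0.75)
  expect_equal(roc_auc(c(2, 1, 2, 1), truth), 1)
  expect_equal(roc_auc(rep(1, 4), truth), 0.5)
  expect_error(roc_auc(1:3, rep("absence", 3)), "single class")
})

test_that("roc_auc equals the all-pairs oracle and is antisymmetric", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    truth <- c("presence", "absence",
               sample(c("presence", "absence"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(scores, truth), oracle_auc(scores, truth))
    expect_equal(roc_auc(scores, truth), 1 - roc_auc(-scores, truth))
  }
})

test_that("repeated holdout: oracle features give BAC 100, SD 0", {
  set.seed(40)
  y <- factor(rep(c("absence", "presence"), each = 20),
              levels = c("absence", "presence"))
  X <- cbind(leak = as.numeric(y) + rnorm(40, 0, 1e-4),
             junk = rnorm(40))
  cfg <- svm_config(gamma = 1, cost = 100)
  res <- repeated_holdout(X, y, cfg, n_reps = 20, seed = 4)
  expect_equal(res$bac_mean, 100)
  expect_equal(res$bac_sd, 0)
  expect_equal(res$auc, 1)

  res2 <- repeated_holdout(X, y, cfg, n_reps = 20, seed = 4)
  expect_identical(res, res2)   # determinism contract

  # adding reps never reshuffles earlier reps (derived substreams)
  res3 <- repeated_holdout(X, y, cfg, n_reps = 25, seed = 4)
  expect_equal(res3$bac_mean, 100)
})

test_that("uninformative features give BAC near 50", {
  set.seed(12)
  y <- factor(rep(c("absence", "presence"), each = 40),
              levels = c("absence", "presence"))
  X <- cbind(a = rnorm(80), b = rnorm(80))
  res <- repeated_holdout(X, y, svm_config(gamma = 1, cost = 1),
                          n_reps = 200, seed = 5)
  expect_lt(abs(res$bac_mean - 50), 3)
})

test_that("learning curve at fraction 1 reproduces repeated_holdout", {
  b <- make_blobs(30, sep = 3, seed = 13)
  cfg <- svm_config(gamma = 0.5, cost = 1)
  lc <- learning_curve(b$X, b$y, cfg, fractions = c(1, 0.5), n_reps = 10,
                       seed = 6)
  direct <- repeated_holdout(b$X, b$y, cfg, n_reps = 10, seed = 6)
  expect_equal(lc$bac_mean[1], direct$bac_mean)
  expect_equal(lc$bac_sd[1], direct$bac_sd)
  expect_equal(lc$n, c(60L, 30L))
  expect_equal(learning_curve(b$X, b$y, cfg, n_reps = 1, seed = 1)$fraction,
               seq(0.9, 0.1, by = -0.1))
  expect_error(learning_curve(b$X, b$y, cfg, fractions = 1.5), "fractions")
})

test_that("match_detections scores greedily with one-to-one pairs", {
  truth <- selection_table(1:10, "s", seq(0, 90, by = 10),
                           seq(2, 92, by = 10), 1000, 2000,
                           class_label = rep(1:2, 5))
  sc <- match_detections(truth, truth)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)

  none <- match_detections(truth[0, ], truth)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)

  # 9 of 10 matched
  det <- truth[-4, ]
  sc9 <- match_detections(det, truth)
  expect_equal(sc9$recall, 0.9)
  expect_equal(sc9$n_matched, 9L)
  expect_equal(sort(sc9$pairs$class_label),
               sort(truth$class_label[-4]))

  # below-threshold overlap does not match
  shifted <- truth
  shifted$begin_time <- shifted$begin_time + 1.5
  shifted$end_time <- shifted$end_time + 1.5
  expect_equal(match_detections(shifted, truth)$n_matched, 0L)
  expect_equal(match_detections(shifted, truth,
                                overlap_threshold = 0.2)$n_matched, 10L)
})
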