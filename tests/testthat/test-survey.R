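# A small trained model shared by the survey tests.
survey_model <- local({
  corpus <- make_training_corpus(lapply(41:43, function(s)
    unit_spec(s, n_target_songs = 5L)))
  cfg <- svm_config(gamma = 0.1, cost = 10)
  list(model = train_classifier(feature_matrix(corpus$features),
                                corpus$labels, cfg),
       corpus = corpus)
})

test_that("scan_recordings classifies synthetic files end to end", {
  out_dir <- withr::local_tempdir()
  easy <- synth_soundscape(unit_spec(44, n_target_songs = 5L,
                                     distractors = list()))
  silence <- audio_clip(withr::with_seed(45, rnorm(16000 * 8, 0, 1e-4)),
                        16000, source_id = "silence")
  scan <- scan_recordings(list(easy$clip, silence), detector_config(),
                          survey_model$model, out_dir = out_dir)
  expect_s3_class(scan, "scan_result")
  expect_equal(scan[[1]]$n_positive, 5L)
  expect_equal(scan[[2]]$n_candidates, 0L)
  expect_equal(scan[[2]]$n_positive, 0L)

  # conservation: positives in memory equal positives in persisted tables
  persisted <- sum(vapply(scan, function(r) {
    tab <- read_selection_table(
      file.path(out_dir, paste0(r$source_id, "_selections.txt")))
    sum(tab$class_label == 1L)
  }, numeric(1)))
  expect_equal(persisted, sum(vapply(scan, `[[`, integer(1), "n_positive")))

  # unreadable files are skipped, not fatal
  scan2 <- scan_recordings("no_such_file.wav", detector_config(),
                           survey_model$model)
  expect_true(scan2[[1]]$skipped)
  expect_equal(scan2[[1]]$n_candidates, 0L)
})

test_that("presence_report flags presence and caps the review table", {
  easy <- synth_soundscape(unit_spec(46, n_target_songs = 5L,
                                     distractors = list()))
  scan <- scan_recordings(list(easy$clip), detector_config(),
                          survey_model$model)
  rep1 <- presence_report(scan, top_n = 3L)
  expect_true(rep1$presence)
  expect_equal(nrow(rep1$review), 3L)
  expect_true(all(diff(rep1$review$score) <= 0))
  # the review table holds the highest-scoring positives
  all_pos <- scan[[1]]$candidates[scan[[1]]$candidates$class_label == 1L, ]
  expect_equal(sort(rep1$review$score, decreasing = TRUE),
               head(sort(all_pos$score, decreasing = TRUE), 3))

  quiet <- audio_clip(withr::with_seed(47, rnorm(16000 * 8, 0, 1e-4)),
                      16000, source_id = "quiet")
  rep0 <- presence_report(scan_recordings(list(quiet), detector_config(),
                                          survey_model$model))
  expect_false(rep0$presence)
  expect_equal(nrow(rep0$review), 0L)
})

test_that("abundance arithmetic is exact and aggregates to point means", {
  scan <- structure(list(
    list(source_id = "a1", skipped = FALSE, n_positive = 12L, minutes = 10),
    list(source_id = "a2", skipped = FALSE, n_positive = 2L, minutes = 10),
    list(source_id = "b1", skipped = FALSE, n_positive = 0L, minutes = 5)),
    class = "scan_result")
  meta <- data.frame(source_id = c("a1", "a2", "b1"),
                     site = c("S1", "S1", "S2"),
                     point = c("P1", "P1", "P2"),
                     minutes = c(4, 2, 5))
  ab <- abundance_table(scan, meta)
  expect_equal(ab$records$calls_per_minute, c(3, 1, 0))
  expect_equal(ab$point_means$calls_per_minute[
    ab$point_means$point == "P1"], 2)
  expect_error(abundance_table(scan, meta[-1, ]), "a1")

  # metadata minutes take precedence over file duration (duty cycling)
  expect_equal(ab$records$minutes, c(4, 2, 5))
})

test_that("compare_sites prefers the site model when means differ", {
  make_records <- function(mu, seed, sd = 0.2) {
    set.seed(seed)
    do.call(rbind, lapply(seq_along(mu), function(s)
      do.call(rbind, lapply(1:3, function(p) data.frame(
        site = paste0("S", s), point = paste0("S", s, "P", p),
        calls_per_minute = rnorm(4, mu[s], sd))))))
  }
  cmp <- compare_sites(make_records(c(1, 5), seed = 51))
  expect_equal(cmp$preferred, "site")
  expect_gt(cmp$delta_aic, 2)

  expect_error(compare_sites(make_records(1, seed = 52)), "2 sites")
  one_pt <- make_records(c(1, 5), seed = 53)
  one_pt$point <- ifelse(one_pt$site == "S1", "S1P1", one_pt$point)
  expect_error(compare_sites(one_pt), "2 points per site")
})

test_that("equal-mean sites are rarely declared different", {
  verdicts <- vapply(1:20, function(s) {
    set.seed(60 + s)
    rec <- do.call(rbind, lapply(1:2, function(site)
      do.call(rbind, lapply(1:3, function(p) data.frame(
        site = paste0("S", site), point = paste0("S", site, "P", p),
        calls_per_minute = rnorm(4, 2 + rnorm(1, 0, 0.3), 0.5))))))
    compare_sites(rec)$preferred
  }, character(1))
  expect_gte(mean(verdicts %in% c("equivalent", "null")), 0.9)
})
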