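test_that("detector_config validates its invariants", {
  expect_error(detector_config(min_freq = 6100, max_freq = 1000), "min_freq")
  expect_error(detector_config(min_duration = 5, max_duration = 0.5),
               "min_duration")
  expect_error(detector_config(noise_percentile = 1.2), "noise_percentile")
  expect_error(detector_config(snr_threshold = 0), "snr_threshold")
  cfg <- detector_config()
  expect_equal(c(cfg$min_freq, cfg$max_freq), c(1000, 6100))
  expect_equal(c(cfg$min_duration, cfg$max_duration), c(0.5, 5))
})

test_that("noise profile is the block percentile of per-bin magnitude", {
  cfg <- detector_config(min_freq = 100, max_freq = 400, noise_block = 100)
  spec <- raw_spectrogram(matrix(2.5, nrow = 101, ncol = 50))
  np <- estimate_noise_profile(spec, cfg)
  expect_true(all(np$level == 2.5))

  # 90% of frames at 1.0, 10% at 100.0, percentile 0.5 -> level 1.0
  set.seed(3)
  mag <- matrix(1, nrow = 101, ncol = 200)
  hot <- sample(200, 20)
  mag[20, hot] <- 100
  spec2 <- raw_spectrogram(mag)
  np2 <- estimate_noise_profile(spec2, cfg)
  expect_equal(unique(np2$level[20, ]), 1.0)
  expect_equal(np2$level[20, 1], oracle_percentile(mag[20, ], 0.5))

  expect_error(estimate_noise_profile(
    spec, detector_config(min_freq = 100, max_freq = 9000)),
    "outside the spectrogram")
})

test_that("a tone burst is detected once with accurate extent", {
  sr <- 16000
  noise <- withr::with_seed(11, rnorm(sr * 12, 0, 0.01))
  t <- seq(0, 2 - 1 / sr, by = 1 / sr)
  burst <- 10^(30 / 20) * 0.01 * sqrt(5100 / (sr / 2)) * sqrt(2) *
    sin(2 * pi * 3000 * t)
  x <- noise
  x[(5 * sr + 1):(5 * sr + length(t))] <- x[(5 * sr + 1):(5 * sr + length(t))] + burst
  spec <- compute_spectrogram(audio_clip(x, sr), 512L, 256L)
  cfg <- detector_config()
  sel <- detect_candidates(spec, cfg)
  expect_equal(nrow(sel), 1L)
  inter <- min(sel$end_time, 7) - max(sel$begin_time, 5)
  expect_gte(inter / 2, 0.9)
  expect_lt(abs(sel$low_freq - 3000), 300)
  expect_lt(abs(sel$high_freq - 3000), 300)

  # same burst but 0.2 s: below min_duration -> nothing
  x2 <- noise
  x2[(5 * sr + 1):(5 * sr + 0.2 * sr)] <-
    x2[(5 * sr + 1):(5 * sr + 0.2 * sr)] + burst[1:(0.2 * sr)]
  expect_equal(nrow(detect_candidates(
    compute_spectrogram(audio_clip(x2, sr), 512L, 256L), cfg)), 0L)

  # 8 kHz burst is out of the 1000-6100 band -> nothing (use sr 22050)
  sr2 <- 22050
  noise2 <- withr::with_seed(12, rnorm(sr2 * 12, 0, 0.01))
  t2 <- seq(0, 2 - 1 / sr2, by = 1 / sr2)
  x3 <- noise2
  seg <- (5 * sr2 + 1):(5 * sr2 + length(t2))
  x3[seg] <- x3[seg] + 0.3 * sin(2 * pi * 8000 * t2)
  expect_equal(nrow(detect_candidates(
    compute_spectrogram(audio_clip(x3, sr2), 512L, 256L), cfg)), 0L)
})

test_that("detections match the brute-force oracle exactly", {
  set.seed(21)
  for (rep in 1:12) {
    nb <- sample(49:50, 1)  # keep the frequency axis wide enough for every cfg band
    nf <- sample(20:50, 1)
    mag <- matrix(rexp(nb * nf, rate = 2), nb, nf)
    # plant a few hot patches
    for (k in seq_len(sample(1:3, 1))) {
      r0 <- sample(nb - 4, 1); c0 <- sample(nf - 6, 1)
      mag[r0:(r0 + 3), c0:(c0 + sample(3:6, 1))] <- rexp(1, 0.1) + 5
    }
    spec <- raw_spectrogram(mag, sample_rate = 1000, hop = 100,
                            window_length = 200)
    cfg <- detector_config(
      min_freq = sample(c(5, 25, 50), 1),
      max_freq = sample(c(120, 200, 240), 1),
      min_duration = 0.2, max_duration = 3,
      snr_threshold = sample(c(6, 10, 14), 1),
      noise_percentile = sample(c(0.25, 0.5, 0.75), 1),
      noise_block = sample(c(1, 2, 100), 1),
      min_separation = sample(c(0, 0.15, 0.35), 1),
      min_occupancy = sample(c(0.3, 0.5, 0.8), 1))
    got <- detect_candidates(spec, cfg)
    want <- oracle_detect(spec, cfg)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$begin_time, want$begin_time)
      expect_equal(got$end_time, want$end_time)
      expect_equal(got$low_freq, want$low_freq)
      expect_equal(got$high_freq, want$high_freq)
    }
  }
})

test_that("detections respect duration bounds and never overlap", {
  ss <- synth_soundscape(unit_spec(5))
  spec <- compute_spectrogram(ss$clip, 512L, 256L)
  cfg <- detector_config()
  sel <- detect_candidates(spec, cfg)
  if (nrow(sel) > 1L) {
    expect_true(all(sel$begin_time[-1] >= sel$end_time[-nrow(sel)]))
  }
  durs <- sel$end_time - sel$begin_time
  expect_true(all(durs >= cfg$min_duration & durs <= cfg$max_duration))
})

test_that("raising the SNR threshold never adds above-threshold frames", {
  ss <- synth_soundscape(unit_spec(6))
  spec <- compute_spectrogram(ss$clip, 512L, 256L)
  prev <- Inf
  for (snr in c(5, 10, 15, 20)) {
    cfg <- detector_config(snr_threshold = snr)
    noise <- estimate_noise_profile(spec, cfg)
    n_marked <- sum(songsvm:::band_threshold_mask(spec, noise, cfg))
    expect_lte(n_marked, prev)
    prev <- n_marked
  }
})

test_that("tune_detector maximizes recall with tie-breaks", {
  ss <- synth_soundscape(unit_spec(7))
  clips <- list(ss$clip); truths <- list(ss$truth)

  one <- detector_config()
  expect_identical(unclass(tune_detector(clips, truths, list(one)))[
    names(unclass(one))], unclass(one))

  # only one config's band contains the songs (targets live at 2500-5800)
  wrong_band <- detector_config(min_freq = 6500, max_freq = 7900)
  got <- tune_detector(clips, truths, list(wrong_band, one))
  expect_equal(c(got$min_freq, got$max_freq), c(1000, 6100))
  expect_gt(attr(got, "recall"), 0.9)

  # equal recall, fewer false positives wins: a permissive SNR admits more
  # noise-only detections at equal recall
  permissive <- detector_config(snr_threshold = 6, min_occupancy = 0.3)
  strict <- detector_config()
  got2 <- tune_detector(clips, truths, list(permissive, strict))
  expect_lte(attr(got2, "false_positives"),
             attr(tune_detector(clips, truths, list(permissive)),
                  "false_positives"))
  expect_error(tune_detector(clips, truths, list()), "empty")
})
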