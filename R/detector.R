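#' Band-limited energy detector configuration
#'
#' Parameters of the detector that segments candidate songs: sections of
#' signal whose in-band energy exceeds an estimated background-noise level by
#' an SNR threshold, within a frequency band and a duration window. Defaults
#' encode the target species' song envelope: 0.5–5 s between 1000 and
#' 6100 Hz.
#'
#' @param min_freq,max_freq analysis band in Hz (`0 < min_freq < max_freq`).
#' @param min_duration,max_duration admissible detection durations, seconds.
#' @param snr_threshold amplitude SNR threshold in dB (compared as
#'   `20*log10`); a frame is marked when its band-summed magnitude exceeds
#'   the band-summed noise level times `10^(snr_threshold/20)`.
#' @param noise_percentile percentile (in `(0,1)`) of per-bin magnitude used
#'   as the noise level.
#' @param noise_block block length in seconds for noise estimation; the noise
#'   level is the per-bin order-statistic percentile within consecutive
#'   blocks (last partial block merges into the previous one).
#' @param min_separation gap in seconds below which adjacent detections merge.
#' @param min_occupancy minimum fraction of above-threshold frames inside a
#'   detection.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(min_freq = 1000, max_freq = 6100,
                            min_duration = 0.5, max_duration = 5,
                            snr_threshold = 10, noise_percentile = 0.5,
                            noise_block = 10, min_separation = 0.1,
                            min_occupancy = 0.5) {
  if (!(min_freq > 0 && min_freq < max_freq))
    stop("require 0 < min_freq < max_freq")
  if (!(min_duration > 0 && min_duration < max_duration))
    stop("require 0 < min_duration < max_duration")
  if (!(noise_percentile > 0 && noise_percentile < 1))
    stop("noise_percentile must lie in (0, 1)")
  if (!(snr_threshold > 0)) stop("snr_threshold must be positive (dB)")
  if (!(noise_block > 0)) stop("noise_block must be positive (s)")
  if (min_separation < 0) stop("min_separation must be >= 0")
  if (!(min_occupancy > 0 && min_occupancy <= 1))
    stop("min_occupancy must lie in (0, 1]")
  structure(list(min_freq = min_freq, max_freq = max_freq,
                 min_duration = min_duration, max_duration = max_duration,
                 snr_threshold = snr_threshold,
                 noise_percentile = noise_percentile,
                 noise_block = noise_block, min_separation = min_separation,
                 min_occupancy = min_occupancy),
            class = "detector_config")
}

# Frame start times in seconds (frame t covers [(t-1)*hop, (t-1)*hop + win)).
frame_starts <- function(spec) {
  (seq_along(spec$time_axis) - 1L) * spec$hop / spec$sample_rate
}

#' Estimate the per-bin background-noise profile
#'
#' The background noise of a sound file is estimated per frequency bin as the
#' `noise_percentile` order statistic of that bin's magnitudes within
#' consecutive `noise_block`-second blocks, giving a piecewise-constant,
#' deterministic noise level robust to sparse song energy.
#'
#' @param spec a [compute_spectrogram()] result covering the analysis band.
#' @param cfg a [detector_config()].
#' @return An object of class `noise_profile` with `level` (matrix, band bins
#'   x frames), `band_bins` (row indices into the spectrogram), `freq` (Hz of
#'   those bins) and `block_id` per frame.
#' @export
estimate_noise_profile <- function(spec, cfg) {
  stopifnot(inherits(spec, "spectrogram"), inherits(cfg, "detector_config"))
  if (cfg$min_freq >= cfg$max_freq)
    stop("empty analysis band: min_freq >= max_freq")
  if (cfg$max_freq > max(spec$freq_axis) || cfg$min_freq < min(spec$freq_axis))
    stop("analysis band lies outside the spectrogram frequency range")
  band <- which(spec$freq_axis >= cfg$min_freq & spec$freq_axis <= cfg$max_freq)
  if (length(band) == 0L) stop("no frequency bins inside the analysis band")

  starts <- frame_starts(spec)
  n_frames <- length(starts)
  n_blocks <- max(1L, floor(spec$clip_duration / cfg$noise_block))
  block <- pmin(floor(starts / cfg$noise_block), n_blocks - 1L) + 1L
  level <- matrix(0, nrow = length(band), ncol = n_frames)
  for (b in seq_len(n_blocks)) {
    cols <- which(block == b)
    sub <- spec$magnitude[band, cols, drop = FALSE]
    level[, cols] <- apply(sub, 1L, quantile_type1, p = cfg$noise_percentile)
  }
  structure(list(level = level, band_bins = band,
                 freq = spec$freq_axis[band], block_id = block,
                 noise_percentile = cfg$noise_percentile,
                 noise_block = cfg$noise_block),
            class = "noise_profile")
}

# Frames whose band-summed magnitude exceeds the band-summed noise level
# scaled by the linear SNR threshold. Used by detect_candidates and by the
# monotonicity property tests.
band_threshold_mask <- function(spec, noise, cfg) {
  thr <- 10^(cfg$snr_threshold / 20)
  bandmag <- spec$magnitude[noise$band_bins, , drop = FALSE]
  colSums(bandmag) > colSums(noise$level) * thr
}

#' Detect candidate songs
#'
#' Marks frames whose band-summed magnitude exceeds the noise level by the
#' SNR threshold, merges maximal runs of marked frames separated by gaps
#' shorter than `min_separation`, and keeps runs whose duration lies in
#' `[min_duration, max_duration]` with occupancy (fraction of marked frames)
#' at least `min_occupancy`. Each detection's frequency extent is the range
#' of band bins that exceeded their own noise level in at least
#' `min_occupancy` of the run's marked frames, padded by half a bin; runs
#' with no such bin fall back to the full analysis band.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param cfg a [detector_config()].
#' @param noise optional precomputed [estimate_noise_profile()] result.
#' @return A selection data frame (see [selection_table()]) ordered by begin
#'   time; non-overlapping after merging.
#' @export
detect_candidates <- function(spec, cfg, noise = NULL) {
  stopifnot(inherits(spec, "spectrogram"), inherits(cfg, "detector_config"))
  if (is.null(noise)) noise <- estimate_noise_profile(spec, cfg)
  thr <- 10^(cfg$snr_threshold / 20)
  marked <- band_threshold_mask(spec, noise, cfg)

  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) > 0L) {
    # merge runs separated by a gap shorter than min_separation
    sec_per_frame <- spec$hop / spec$sample_rate
    merged <- list()
    cur <- runs[1L, ]
    for (i in seq_len(nrow(runs))[-1L]) {
      gap <- (runs[i, 1L] - cur[2L] - 1L) * sec_per_frame
      if (gap < cfg$min_separation) cur[2L] <- runs[i, 2L]
      else { merged[[length(merged) + 1L]] <- cur; cur <- runs[i, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    runs <- do.call(rbind, merged)
  }

  bandmag <- spec$magnitude[noise$band_bins, , drop = FALSE]
  binw <- spec$freq_axis[2L] - spec$freq_axis[1L]
  out <- list()
  for (i in seq_len(NROW(runs))) {
    s <- runs[i, 1L]; e <- runs[i, 2L]
    begin <- (s - 1L) * spec$hop / spec$sample_rate
    end <- min(((e - 1L) * spec$hop + spec$window_length) / spec$sample_rate,
               spec$clip_duration)
    dur <- end - begin
    if (dur < cfg$min_duration || dur > cfg$max_duration) next
    occ <- sum(marked[s:e]) / (e - s + 1L)
    if (occ < cfg$min_occupancy) next
    cols <- (s:e)[marked[s:e]]
    # a bin counts as occupied only if it exceeds its own noise level in at
    # least min_occupancy of the run's marked frames (one noisy frame must
    # not widen the box)
    hot <- which(rowMeans(bandmag[, cols, drop = FALSE] >
                          noise$level[, cols, drop = FALSE] * thr) >=
                 cfg$min_occupancy)
    if (length(hot) > 0L) {
      lo <- max(cfg$min_freq, noise$freq[min(hot)] - binw / 2)
      hi <- min(cfg$max_freq, noise$freq[max(hot)] + binw / 2)
      if (lo >= hi) { lo <- cfg$min_freq; hi <- cfg$max_freq }
    } else {
      lo <- cfg$min_freq; hi <- cfg$max_freq
    }
    out[[length(out) + 1L]] <-
      data.frame(begin_time = begin, end_time = end, low_freq = lo, high_freq = hi)
  }
  if (length(out) == 0L) return(empty_selection_table(spec$source_id))
  df <- do.call(rbind, out)
  df <- df[order(df$begin_time), , drop = FALSE]
  selection_table(selection_id = seq_len(nrow(df)), source_id = spec$source_id,
                  begin_time = df$begin_time, end_time = df$end_time,
                  low_freq = df$low_freq, high_freq = df$high_freq)
}

#' Tune the detector over a configuration grid
#'
#' Mirrors the interactive search for the noise-parameter configuration that
#' maximizes the selection of true songs: every candidate configuration is
#' run on every labeled clip, recall of the truth selections (temporal
#' overlap matching, see [match_detections()]) is pooled across clips, and
#' the best-recall configuration is returned. Ties break toward fewer false
#' detections, then toward earlier grid position.
#'
#' @param clips list of [audio_clip()]s.
#' @param truths list of truth selection tables aligned with `clips`.
#' @param grid list of [detector_config()] candidates.
#' @param window_length,hop,window_name spectrogram parameters.
#' @param overlap_threshold minimum intersection/truth-duration to count a
#'   match.
#' @return The winning `detector_config`, with attributes `recall` and
#'   `false_positives`.
#' @export
tune_detector <- function(clips, truths, grid, window_length = 512L,
                          hop = window_length %/% 2L, window_name = "hann",
                          overlap_threshold = 0.5) {
  if (length(grid) == 0L) stop("empty detector grid")
  if (length(clips) == 0L || length(clips) != length(truths))
    stop("need at least one labeled (clip, truth) pair")
  specs <- lapply(clips, compute_spectrogram, window_length = window_length,
                  hop = hop, window_name = window_name)
  best <- NULL; best_recall <- -1; best_fp <- Inf
  for (g in seq_along(grid)) {
    cfg <- grid[[g]]
    n_truth <- 0L; n_matched <- 0L; n_det <- 0L
    for (i in seq_along(specs)) {
      det <- detect_candidates(specs[[i]], cfg)
      sc <- match_detections(det, truths[[i]],
                             overlap_threshold = overlap_threshold)
      n_truth <- n_truth + sc$n_truth
      n_matched <- n_matched + sc$n_matched
      n_det <- n_det + sc$n_detected
    }
    recall <- if (n_truth > 0L) n_matched / n_truth else 0
    fp <- n_det - n_matched
    if (recall > best_recall || (recall == best_recall && fp < best_fp)) {
      best <- cfg; best_recall <- recall; best_fp <- fp
    }
  }
  attr(best, "recall") <- best_recall
  attr(best, "false_positives") <- best_fp
  best
}
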