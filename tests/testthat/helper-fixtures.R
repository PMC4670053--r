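# Shared fixtures: everything is generated in code at test time.

# Pure tone clip.
tone_clip <- function(freq = 3000, duration = 1, sr = 16000, amp = 0.5,
                      source_id = "tone") {
  t <- seq(0, duration - 1 / sr, by = 1 / sr)
  audio_clip(amp * sin(2 * pi * freq * t), sr, source_id = source_id)
}

# Small soundscape for unit tests (cheap: 16 kHz, 30 s).
unit_spec <- function(seed = 1L, ...) {
  args <- list(duration = 30, sample_rate = 16000, n_target_songs = 4L,
               target_snr_db = 25, distractors = default_distractors(2L),
               noise_level = 0.01, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(soundscape_spec, args)
}

# Two-class Gaussian blob features.
make_blobs <- function(n_per_class = 50, sep = 4, seed = 1, p = 2) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, 0), ncol = p),
             matrix(rnorm(n_per_class * p, sep), ncol = p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = factor(rep(c("absence", "presence"), each = n_per_class),
                         levels = c("absence", "presence")))
}

# Random valid selection table on the writer's precision grid (4 dp times,
# 1 dp freqs) so write/read round trips are exact.
random_selections <- function(n, seed = 1, source_id = "fix") {
  set.seed(seed)
  begin <- round(sort(runif(n, 0, 50)), 4)
  dur <- round(runif(n, 0.5, 3), 4)
  lo <- round(runif(n, 500, 3000), 1)
  selection_table(selection_id = seq_len(n), source_id = source_id,
                  begin_time = begin, end_time = begin + dur,
                  low_freq = lo, high_freq = lo + round(runif(n, 100, 2000), 1),
                  class_label = sample(0:3, n, replace = TRUE))
}

# A spectrogram object built directly from a magnitude matrix (for detector
# oracle tests that don't need audio).
raw_spectrogram <- function(magnitude, sample_rate = 1000, hop = 100,
                            window_length = 200, source_id = "raw") {
  n_frames <- ncol(magnitude)
  structure(list(
    magnitude = magnitude,
    freq_axis = (seq_len(nrow(magnitude)) - 1) * sample_rate / window_length,
    time_axis = ((seq_len(n_frames) - 1) * hop + window_length / 2) / sample_rate,
    window_length = as.integer(window_length), hop = as.integer(hop),
    window_name = "rectangular", sample_rate = sample_rate,
    source_id = source_id,
    clip_duration = ((n_frames - 1) * hop + window_length) / sample_rate),
    class = "spectrogram")
}
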