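# Independent brute-force oracles. These deliberately re-derive results with
# plain loops and never call the implementation paths they check.

# Order-statistic percentile by full sort.
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  xs[max(1, ceiling(p * length(xs)))]
}

# AUC by all-pairs concordance with ties counted one half.
oracle_auc <- function(scores, truth) {
  pos <- which(truth == "presence")
  neg <- which(truth == "absence")
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1
                 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Frame-by-frame band-limited energy detection: threshold, gap-merge, filter.
# Returns a data frame of begin/end/low/high (no ids).
oracle_detect <- function(spec, cfg) {
  band <- which(spec$freq_axis >= cfg$min_freq & spec$freq_axis <= cfg$max_freq)
  n_frames <- ncol(spec$magnitude)
  starts <- (seq_len(n_frames) - 1) * spec$hop / spec$sample_rate
  n_blocks <- max(1, floor(spec$clip_duration / cfg$noise_block))
  block <- pmin(floor(starts / cfg$noise_block), n_blocks - 1) + 1

  level <- matrix(0, length(band), n_frames)
  for (b in seq_len(n_blocks)) {
    cols <- which(block == b)
    for (r in seq_along(band))
      level[r, cols] <- oracle_percentile(spec$magnitude[band[r], cols],
                                          cfg$noise_percentile)
  }
  thr <- 10^(cfg$snr_threshold / 20)
  marked <- logical(n_frames)
  for (t in seq_len(n_frames))
    marked[t] <- sum(spec$magnitude[band, t]) > sum(level[, t]) * thr

  # maximal runs
  runs <- list(); s <- NA
  for (t in seq_len(n_frames)) {
    if (marked[t] && is.na(s)) s <- t
    if (!marked[t] && !is.na(s)) { runs[[length(runs) + 1]] <- c(s, t - 1); s <- NA }
  }
  if (!is.na(s)) runs[[length(runs) + 1]] <- c(s, n_frames)
  # gap merge
  spf <- spec$hop / spec$sample_rate
  merged <- list()
  for (r in runs) {
    if (length(merged) > 0) {
      prev <- merged[[length(merged)]]
      if ((r[1] - prev[2] - 1) * spf < cfg$min_separation) {
        merged[[length(merged)]] <- c(prev[1], r[2]); next
      }
    }
    merged[[length(merged) + 1]] <- r
  }
  binw <- spec$freq_axis[2] - spec$freq_axis[1]
  out <- list()
  for (r in merged) {
    begin <- (r[1] - 1) * spec$hop / spec$sample_rate
    end <- min(((r[2] - 1) * spec$hop + spec$window_length) / spec$sample_rate,
               spec$clip_duration)
    dur <- end - begin
    if (dur < cfg$min_duration || dur > cfg$max_duration) next
    if (sum(marked[r[1]:r[2]]) / (r[2] - r[1] + 1) < cfg$min_occupancy) next
    hot <- integer(0)
    run_cols <- (r[1]:r[2])[marked[r[1]:r[2]]]
    for (bi in seq_along(band)) {
      n_over <- 0
      for (t in run_cols)
        if (spec$magnitude[band[bi], t] > level[bi, t] * thr)
          n_over <- n_over + 1
      if (n_over / length(run_cols) >= cfg$min_occupancy)
        hot <- c(hot, bi)
    }
    if (length(hot) > 0) {
      lo <- max(cfg$min_freq, spec$freq_axis[band[min(hot)]] - binw / 2)
      hi <- min(cfg$max_freq, spec$freq_axis[band[max(hot)]] + binw / 2)
      if (lo >= hi) { lo <- cfg$min_freq; hi <- cfg$max_freq }
    } else { lo <- cfg$min_freq; hi <- cfg$max_freq }
    out[[length(out) + 1]] <- data.frame(begin_time = begin, end_time = end,
                                         low_freq = lo, high_freq = hi)
  }
  if (length(out) == 0)
    return(data.frame(begin_time = numeric(0), end_time = numeric(0),
                      low_freq = numeric(0), high_freq = numeric(0)))
  do.call(rbind, out)
}

# Brute-force DFT magnitude of one frame.
oracle_dft_mag <- function(x) {
  N <- length(x)
  sapply(0:(N %/% 2), function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(N - 1)) / N)))
  })
}
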