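# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible 32-bit sub-seed from (seed, k). Repetition k of a
# procedure gets its own substream so changing n_reps never reshuffles the
# splits of earlier repetitions.
derive_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 1048573) * 48271 + (as.numeric(k) %% 1048573) * 16807
  as.integer(s %% 2147483647) + 1L
}

# Order statistic percentile (inverted ECDF, quantile type 1): the smallest
# x with ECDF(x) >= p. Deterministic and trivially reproducible by oracle.
quantile_type1 <- function(x, p) {
  k <- max(1L, ceiling(p * length(x)))
  sort(x, partial = k)[k]
}

# Stratified train indices: round(fraction * n_k) per class, clamped so each
# class keeps at least one row on both sides of the split.
stratified_train_idx <- function(labels, fraction) {
  idx <- split(seq_along(labels), labels)
  idx <- idx[lengths(idx) > 0L]
  unlist(lapply(idx, function(ii) {
    k <- round(fraction * length(ii))
    k <- min(max(k, 1L), length(ii) - 1L)
    ii[sample.int(length(ii), k)]
  }), use.names = FALSE)
}

# Largest-remainder apportionment of n into parts proportional to `fractions`
# (sums preserved, deterministic; ties go to the earlier class).
largest_remainder <- function(n, fractions) {
  ideal <- n * fractions / sum(fractions)
  base <- floor(ideal)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(ideal - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
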