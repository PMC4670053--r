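#' Feature schema
#'
#' Names, in stable order, of the 16 robust per-selection acoustic features
#' used as classifier inputs. All are computed from the spectrogram magnitude
#' clipped to the selection box; energy percentiles use the cumulative energy
#' distribution, entropies the energy distribution over bins (log base 2).
#' `peak_power_db` and `avg_power_db` are relative to the loudest cell of the
#' whole spectrogram, so every feature except `energy` is invariant to
#' uniform amplitude scaling of the clip.
#'
#' @return Character vector of feature names.
#' @export
feature_schema <- function() {
  c("duration", "bandwidth", "low_freq", "high_freq", "peak_freq",
    "center_freq", "freq_5pct", "freq_95pct", "peak_time_rel",
    "time_5pct", "time_95pct", "aggregate_entropy", "average_entropy",
    "peak_power_db", "avg_power_db", "energy")
}

#' Measure acoustic features of one selection
#'
#' @param spec a [compute_spectrogram()] result.
#' @param sel one-row selection data frame (or a list with `begin_time`,
#'   `end_time`, `low_freq`, `high_freq`).
#' @return Named numeric vector following [feature_schema()]. Time
#'   percentiles (`time_5pct`, `time_95pct`) are offsets in seconds from the
#'   selection start; `peak_time_rel` is a fraction of the duration.
#' @export
measure_selection <- function(spec, sel) {
  stopifnot(inherits(spec, "spectrogram"))
  begin <- as.numeric(sel$begin_time); end <- as.numeric(sel$end_time)
  lo <- as.numeric(sel$low_freq); hi <- as.numeric(sel$high_freq)
  starts <- frame_starts(spec)
  wl_s <- spec$window_length / spec$sample_rate
  tcols <- which(starts < end & (starts + wl_s) > begin)
  rows <- which(spec$freq_axis >= lo & spec$freq_axis <= hi)
  if (length(tcols) == 0L || length(rows) == 0L)
    stop("selection box does not intersect the spectrogram extent")

  sub <- spec$magnitude[rows, tcols, drop = FALSE]
  freqs <- spec$freq_axis[rows]
  centers <- spec$time_axis[tcols]
  dur <- end - begin

  E <- sub^2
  tot <- sum(E)
  out <- c(duration = dur, bandwidth = hi - lo, low_freq = lo, high_freq = hi)
  if (tot <= 0) {
    # silent box: spectral statistics are undefined
    na <- rep(NA_real_, 12L)
    names(na) <- setdiff(feature_schema(), names(out))
    return(c(out, na))
  }
  pf <- rowSums(E) / tot
  pt <- colSums(E) / tot
  cf <- cumsum(pf)
  ct <- cumsum(pt)
  qf <- function(p) freqs[which(cf >= p)[1L]]
  qt <- function(p) centers[which(ct >= p)[1L]]

  pk <- arrayInd(which.max(sub), dim(sub))
  nz <- pf > 0
  agg_H <- -sum(pf[nz] * log2(pf[nz]))
  col_H <- vapply(seq_len(ncol(E)), function(j) {
    p <- E[, j] / sum(E[, j])
    p <- p[p > 0]
    if (length(p) == 0L) NA_real_ else -sum(p * log2(p))
  }, numeric(1))
  gmax <- max(spec$magnitude)

  c(out,
    peak_freq = freqs[pk[1L]],
    center_freq = qf(0.5), freq_5pct = qf(0.05), freq_95pct = qf(0.95),
    peak_time_rel = min(1, max(0, (centers[pk[2L]] - begin) / dur)),
    time_5pct = min(dur, max(0, qt(0.05) - begin)),
    time_95pct = min(dur, max(0, qt(0.95) - begin)),
    aggregate_entropy = agg_H,
    average_entropy = mean(col_H, na.rm = TRUE),
    peak_power_db = 20 * log10(max(sub) / gmax),
    avg_power_db = 20 * log10(mean(sub) / gmax),
    energy = tot)
}

#' Measure all selections of one recording
#'
#' Batch wrapper around [measure_selection()]: one row per selection in
#' stable column order, keyed by (`source_id`, `selection_id`). Selections
#' that error or yield any non-finite feature are excluded; the excluded
#' count is attached as attribute `n_excluded` and reported via `message()`.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param selections a selection data frame for the same recording.
#' @return `data.frame` with key columns plus [feature_schema()] columns
#'   (and `class_label` if the input selections carry one).
#' @export
measure_all <- function(spec, selections) {
  schema <- feature_schema()
  empty <- as.data.frame(c(
    list(source_id = character(0), selection_id = integer(0)),
    stats::setNames(rep(list(numeric(0)), length(schema)), schema)))
  if (nrow(selections) == 0L) return(structure(empty, n_excluded = 0L))

  rows <- vector("list", nrow(selections))
  ok <- logical(nrow(selections))
  for (i in seq_len(nrow(selections))) {
    fv <- tryCatch(measure_selection(spec, selections[i, ]),
                   error = function(e) NULL)
    if (!is.null(fv) && all(is.finite(fv))) {
      rows[[i]] <- fv
      ok[i] <- TRUE
    }
  }
  n_excluded <- sum(!ok)
  if (n_excluded > 0L)
    message(n_excluded, " selection(s) excluded (non-finite features)")
  if (!any(ok)) return(structure(empty, n_excluded = n_excluded))
  feats <- as.data.frame(do.call(rbind, rows[ok]))[, schema]
  out <- cbind(data.frame(source_id = selections$source_id[ok],
                          selection_id = selections$selection_id[ok],
                          stringsAsFactors = FALSE),
               feats)
  if (!is.null(selections$class_label))
    out$class_label <- selections$class_label[ok]
  structure(out, n_excluded = n_excluded)
}

#' Extract the numeric feature matrix from a measurement table
#'
#' Drops key/annotation columns and returns the [feature_schema()] columns as
#' a numeric matrix suitable for [train_classifier()].
#'
#' @param df output of [measure_all()] (or a CSV read of it).
#' @return Numeric matrix with feature column names.
#' @export
feature_matrix <- function(df) {
  schema <- intersect(feature_schema(), names(df))
  as.matrix(df[, schema, drop = FALSE])
}
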