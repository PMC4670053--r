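#' Scan recordings for the target species
#'
#' The testing phase: for each recording, detect candidate songs with the
#' band-limited energy detector, measure features, and classify each
#' candidate with the trained SVM. Unreadable files are skipped (logged in
#' the result, not fatal). Deterministic.
#'
#' @param inputs character vector of WAV paths, or a list of [audio_clip()]s.
#' @param detector_cfg a [detector_config()].
#' @param model a [train_classifier()] result (or [load_model()] output).
#' @param window_length,hop,window_name spectrogram parameters.
#' @param out_dir optional directory: one Raven selection table per recording
#'   is written there (`<source_id>_selections.txt`), with predicted `Class`
#'   (0/1) and decision `Score` columns.
#' @return List of class `scan_result`; one entry per input with `source_id`,
#'   `candidates` (selection table with `class_label` = predicted 0/1 and
#'   `score`), `n_candidates`, `n_positive`, `minutes` (file duration), and
#'   `skipped` (TRUE with `error` when unreadable).
#' @export
scan_recordings <- function(inputs, detector_cfg, model,
                            window_length = 512L, hop = window_length %/% 2L,
                            window_name = "hann", out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- lapply(inputs, function(input) {
    clip <- tryCatch(
      if (inherits(input, "audio_clip")) input else read_wav(input),
      error = function(e) e)
    if (inherits(clip, "error")) {
      return(list(source_id = if (is.character(input)) input else "<clip>",
                  skipped = TRUE, error = conditionMessage(clip),
                  candidates = empty_selection_table(),
                  n_candidates = 0L, n_positive = 0L, minutes = NA_real_))
    }
    gram <- compute_spectrogram(clip, window_length = window_length,
                                hop = hop, window_name = window_name)
    cand <- detect_candidates(gram, detector_cfg)
    if (nrow(cand) > 0L) {
      m <- suppressMessages(measure_all(gram, cand))
      cand <- cand[cand$selection_id %in% m$selection_id, , drop = FALSE]
      if (nrow(cand) > 0L) {
        sc <- decision_scores(model, feature_matrix(m))
        cand$class_label <- ifelse(sc > 0, 1L, 0L)
        cand$score <- sc
      }
    }
    if (nrow(cand) == 0L) {
      cand$class_label <- integer(0)
      cand$score <- numeric(0)
    }
    if (!is.null(out_dir))
      write_selection_table(cand, file.path(
        out_dir, paste0(clip$source_id, "_selections.txt")))
    list(source_id = clip$source_id, skipped = FALSE, candidates = cand,
         n_candidates = nrow(cand), n_positive = sum(cand$class_label == 1L),
         minutes = clip$duration / 60)
  })
  structure(results, class = "scan_result")
}

#' Presence report with a manual-review table
#'
#' Presence is flagged when any candidate is classified positive. Because
#' false positives can be recognized by eye on a spectrogram, the report
#' exports the `top_n` highest-scoring positives as a review selection table
#' for manual confirmation in any spectrogram viewer.
#'
#' @param scan a [scan_recordings()] result.
#' @param top_n cap on review-table rows (default 50).
#' @return List: `presence` (logical), `n_positive`, `n_candidates`,
#'   `n_skipped`, `review` (selection data frame sorted by descending score).
#' @export
presence_report <- function(scan, top_n = 50L) {
  stopifnot(inherits(scan, "scan_result"))
  pos <- lapply(scan, function(r) {
    if (r$skipped || r$n_positive == 0L) return(NULL)
    r$candidates[r$candidates$class_label == 1L, , drop = FALSE]
  })
  pos <- do.call(rbind, pos[!vapply(pos, is.null, logical(1))])
  n_pos <- if (is.null(pos)) 0L else nrow(pos)
  review <- if (n_pos > 0L) {
    pos <- pos[order(-pos$score), , drop = FALSE]
    utils::head(pos, top_n)
  } else empty_selection_table()
  list(presence = n_pos > 0L, n_positive = n_pos,
       n_candidates = sum(vapply(scan, `[[`, integer(1), "n_candidates")),
       n_skipped = sum(vapply(scan, `[[`, logical(1), "skipped")),
       review = review)
}

#' Call-rate relative abundance table
#'
#' Calls per minute = SVM-positive detections in a recording divided by the
#' minutes recorded in that file. Minutes come from the metadata (recorders
#' are duty-cycled, so file duration alone can mislead); when metadata
#' minutes are missing, the scanned file duration is used.
#'
#' @param scan a [scan_recordings()] result.
#' @param metadata `data.frame` with columns `source_id`, `site`, `point` and
#'   optionally `minutes`.
#' @return List of class `abundance_table`: `records` (one row per
#'   recording: `source_id`, `site`, `point`, `n_detections`, `minutes`,
#'   `calls_per_minute`), `point_means`, `site_means`.
#' @export
abundance_table <- function(scan, metadata) {
  stopifnot(inherits(scan, "scan_result"))
  need <- c("source_id", "site", "point")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0L)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  rows <- lapply(scan, function(r) {
    if (r$skipped) return(NULL)
    j <- match(r$source_id, metadata$source_id)
    if (is.na(j)) stop("no metadata for source_id: ", r$source_id)
    minutes <- if (!is.null(metadata$minutes) && !is.na(metadata$minutes[j]))
      metadata$minutes[j] else r$minutes
    if (!is.finite(minutes) || minutes <= 0)
      stop("minutes must be positive for source_id: ", r$source_id)
    data.frame(source_id = r$source_id, site = metadata$site[j],
               point = metadata$point[j], n_detections = r$n_positive,
               minutes = minutes,
               calls_per_minute = r$n_positive / minutes,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  point_means <- stats::aggregate(calls_per_minute ~ site + point,
                                  data = records, FUN = mean)
  site_means <- stats::aggregate(calls_per_minute ~ site,
                                 data = records, FUN = mean)
  structure(list(records = records, point_means = point_means,
                 site_means = site_means),
            class = "abundance_table")
}

#' Compare sites by call rate with linear mixed models
#'
#' Fits two Gaussian linear mixed models of calls per minute with a random
#' intercept per recording point — one intercept-only, one adding the study
#' site as a categorical fixed effect — by maximum likelihood (models differ
#' in fixed effects, so ML, not REML, makes the AICs comparable). Models
#' within 2 AIC units are treated as equally supported.
#'
#' @param records abundance records (`data.frame` from [abundance_table()],
#'   or the `abundance_table` itself) with `calls_per_minute`, `site`,
#'   `point`.
#' @return Object of class `site_comparison`: `aic_null`, `aic_site`,
#'   `delta_aic` (`aic_null - aic_site`), `preferred`
#'   (`"site"`, `"null"` or `"equivalent"`) and the fitted models.
#' @export
compare_sites <- function(records) {
  if (inherits(records, "abundance_table")) records <- records$records
  records$site <- factor(records$site)
  records$point <- factor(records$point)
  if (nlevels(records$site) < 2L)
    stop("insufficient replication: need at least 2 sites")
  pts_per_site <- tapply(records$point, records$site,
                         function(p) length(unique(p)))
  if (any(pts_per_site < 2L))
    stop("insufficient replication: need at least 2 points per site")
  if (any(table(records$point) < 2L))
    stop("insufficient replication: need at least 2 records per point")

  fit <- function(formula) suppressWarnings(suppressMessages(
    lme4::lmer(formula, data = records, REML = FALSE)))
  m0 <- fit(calls_per_minute ~ 1 + (1 | point))
  m1 <- fit(calls_per_minute ~ site + (1 | point))
  aic0 <- stats::AIC(m0); aic1 <- stats::AIC(m1)
  delta <- aic0 - aic1
  preferred <- if (abs(delta) < 2) "equivalent"
               else if (delta > 0) "site" else "null"
  structure(list(aic_null = aic0, aic_site = aic1, delta_aic = delta,
                 preferred = preferred, model_null = m0, model_site = m1),
            class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("AIC null %.2f  site %.2f  dAIC %.2f -> %s\n",
              x$aic_null, x$aic_site, x$delta_aic, x$preferred))
  invisible(x)
}
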