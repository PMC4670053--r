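#' Build a selection table
#'
#' A selection is a rectangular time x frequency box marking one candidate
#' vocalization, following Raven selection-table semantics (seconds from file
#' start, inclusive begin/end). Annotated selections additionally carry a
#' class label: 0 = not the target species (absence); 1 = target song poorly
#' selected / heavily overlapped; 2 = some overlap; 3 = clean selection.
#' Classes 1–3 all mean species presence.
#'
#' @param selection_id positive integer ids.
#' @param source_id recording identifier(s).
#' @param begin_time,end_time selection bounds in seconds, `begin < end`.
#' @param low_freq,high_freq frequency bounds in Hz, `low < high`.
#' @param channel integer channel (default 1).
#' @param class_label optional integer labels in `{0,1,2,3}`.
#' @return A `data.frame` with class `selection_table`.
#' @export
selection_table <- function(selection_id, source_id, begin_time, end_time,
                            low_freq, high_freq, channel = 1L,
                            class_label = NULL) {
  n <- length(selection_id)
  df <- data.frame(selection_id = as.integer(selection_id),
                   source_id = rep_len(as.character(source_id), n),
                   channel = rep_len(as.integer(channel), n),
                   begin_time = as.numeric(begin_time),
                   end_time = as.numeric(end_time),
                   low_freq = rep_len(as.numeric(low_freq), n),
                   high_freq = rep_len(as.numeric(high_freq), n),
                   stringsAsFactors = FALSE)
  if (!is.null(class_label)) df$class_label <- as.integer(class_label)
  validate_selections(df)
  class(df) <- c("selection_table", "data.frame")
  df
}

empty_selection_table <- function(source_id = character(0)) {
  df <- data.frame(selection_id = integer(0), source_id = character(0),
                   channel = integer(0), begin_time = numeric(0),
                   end_time = numeric(0), low_freq = numeric(0),
                   high_freq = numeric(0), stringsAsFactors = FALSE)
  class(df) <- c("selection_table", "data.frame")
  df
}

#' Validate selection invariants
#'
#' Checks `begin_time < end_time`, `low_freq < high_freq`, positive ids and,
#' when `duration` is supplied, containment within the recording.
#'
#' @param df a selection data frame.
#' @param duration optional recording duration in seconds.
#' @return `df`, invisibly; errors on violation.
#' @export
validate_selections <- function(df, duration = NULL) {
  need <- c("selection_id", "source_id", "begin_time", "end_time",
            "low_freq", "high_freq")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("selection table missing column(s): ",
                              paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$selection_id <= 0L)) stop("selection_id must be positive")
  if (any(!is.finite(df$begin_time)) || any(!is.finite(df$end_time)) ||
      any(df$begin_time >= df$end_time))
    stop("selections must satisfy begin_time < end_time")
  if (any(!is.finite(df$low_freq)) || any(!is.finite(df$high_freq)) ||
      any(df$low_freq >= df$high_freq))
    stop("selections must satisfy low_freq < high_freq")
  if (!is.null(duration) && any(df$begin_time < 0 | df$end_time > duration + 1e-9))
    stop("selection times fall outside the recording duration")
  if (!is.null(df$class_label) &&
      any(!df$class_label %in% c(0L, 1L, 2L, 3L)))
    stop("label error: class labels must be in {0, 1, 2, 3}")
  invisible(df)
}

# Raven column dialect.
.raven_required <- c("Selection", "Begin Time (s)", "End Time (s)",
                     "Low Freq (Hz)", "High Freq (Hz)")

#' Read a Raven-style selection table
#'
#' Parses a tab-delimited selection table with the standard columns
#' `Selection`, `Begin Time (s)`, `End Time (s)`, `Low Freq (Hz)`,
#' `High Freq (Hz)`, optional `Channel`, optional `Class` (annotation) and
#' optional `Score`. The `View` column is ignored.
#'
#' @param path path to the tab-delimited table.
#' @param source_id recording identifier to attach; defaults to the file name
#'   without extension.
#' @return A selection `data.frame`; includes `class_label` when a `Class`
#'   column is present and `score` when a `Score` column is present.
#' @export
read_selection_table <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(.raven_required, names(raw))
  if (length(miss) > 0L)
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                   col, bad[1L]))
    x
  }
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  if (nrow(raw) == 0L) return(empty_selection_table())
  cls <- if ("Class" %in% names(raw)) as.integer(num("Class")) else NULL
  df <- selection_table(
    selection_id = as.integer(num("Selection")),
    source_id = source_id,
    begin_time = num("Begin Time (s)"), end_time = num("End Time (s)"),
    low_freq = num("Low Freq (Hz)"), high_freq = num("High Freq (Hz)"),
    channel = if ("Channel" %in% names(raw)) as.integer(num("Channel")) else 1L,
    class_label = cls)
  if ("Score" %in% names(raw)) df$score <- num("Score")
  df
}

#' Write a Raven-style selection table
#'
#' Tab-delimited, UTF-8, decimal point, trailing newline. Times are written
#' with 4 decimals and frequencies with 1, so a write/read round trip is
#' lossless at those precisions. A `Class` column is emitted when the records
#' are annotated, and a `Score` column when decision scores are attached.
#'
#' @param df a selection data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(df, path) {
  validate_selections(df)
  header <- c("Selection", "View", "Channel", "Begin Time (s)", "End Time (s)",
              "Low Freq (Hz)", "High Freq (Hz)")
  has_class <- !is.null(df$class_label)
  has_score <- !is.null(df$score)
  if (has_class) header <- c(header, "Class")
  if (has_score) header <- c(header, "Score")
  lines <- paste(header, collapse = "\t")
  if (nrow(df) > 0L) {
    body <- sprintf("%d\tSpectrogram 1\t%d\t%.4f\t%.4f\t%.1f\t%.1f",
                    df$selection_id, df$channel %||% 1L,
                    df$begin_time, df$end_time, df$low_freq, df$high_freq)
    if (has_class) body <- paste0(body, "\t", df$class_label)
    if (has_score) body <- paste0(body, sprintf("\t%.6f", df$score))
    lines <- c(lines, body)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Binarize four-class annotations into presence/absence
#'
#' Class 0 means target-species absence; classes 1–3 (increasing selection
#' quality) all mean presence.
#'
#' @param df an annotated selection data frame (has `class_label`).
#' @return A list with `presence_count`, `absence_count`, and `binary`, a
#'   factor with levels `c("absence", "presence")` aligned with rows of `df`.
#' @export
binarize_labels <- function(df) {
  if (is.null(df$class_label)) stop("label error: no class labels present")
  if (any(is.na(df$class_label)) ||
      any(!df$class_label %in% c(0L, 1L, 2L, 3L)))
    stop("label error: class labels must be in {0, 1, 2, 3}")
  binary <- factor(ifelse(df$class_label == 0L, "absence", "presence"),
                   levels = c("absence", "presence"))
  list(presence_count = sum(df$class_label != 0L),
       absence_count = sum(df$class_label == 0L),
       binary = binary)
}
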