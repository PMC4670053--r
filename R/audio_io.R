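#' Construct an audio clip
#'
#' The raw survey unit: a mono, real-valued waveform with its sample rate.
#' Amplitudes are dimensionless and normalized to `[-1, 1]`; absolute
#' calibration is irrelevant downstream because the detector thresholds on
#' relative (signal-to-noise) levels.
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz (field recordings use 44100).
#' @param source_id recording identifier carried through the pipeline.
#' @return An object of class `audio_clip` with fields `samples`,
#'   `sample_rate`, `source_id` and derived `duration` (seconds).
#' @export
audio_clip <- function(samples, sample_rate, source_id = "clip") {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("format error: clip must contain at least one sample")
  if (!all(is.finite(samples)))
    stop("amplitudes must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar (Hz)")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         source_id = as.character(source_id),
         duration = length(samples) / sample_rate),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip '%s': %.3f s @ %g Hz>\n",
              x$source_id, x$duration, x$sample_rate))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Reads 8/16/24/32-bit integer PCM. Multi-channel input is mixed down to
#' mono by averaging channels (field data used a single omnidirectional
#' microphone, so channels are interchangeable); samples are scaled to
#' `[-1, 1]` regardless of bit depth.
#'
#' @param path path to a `.wav` file.
#' @param source_id identifier for the clip; defaults to the file name
#'   without extension.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("format error: not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("format error: not a RIFF/WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id, type = "bytes") < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(sz) == 0L || sz < 0L) stop("format error: corrupt chunk in ", path)
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      if (length(fmt_raw) < 16L) stop("format error: truncated fmt chunk")
      u16 <- function(off) {
        as.integer(fmt_raw[off + 1L]) + 256L * as.integer(fmt_raw[off + 2L])
      }
      u32 <- function(off) u16(off) + 65536 * u16(off + 2L)
      fmt <- list(audio_format = u16(0L), n_channels = u16(2L),
                  sample_rate = u32(4L), bits = u16(14L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1L)  # RIFF chunks are word-aligned
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("format error: missing fmt chunk in ", path)
  if (is.null(data_raw)) stop("format error: missing data chunk in ", path)
  if (fmt$audio_format != 1L)
    stop("format error: unsupported WAV encoding (only integer PCM is supported)")
  bits <- fmt$bits
  if (!bits %in% c(8L, 16L, 24L, 32L))
    stop("format error: unsupported bit depth: ", bits)

  n_vals <- length(data_raw) %/% (bits %/% 8L)
  if (n_vals == 0L) stop("format error: WAV file contains no samples")
  v <- switch(as.character(bits),
    "8"  = (as.numeric(data_raw[seq_len(n_vals)]) - 128) / 128,
    "16" = readBin(data_raw, "integer", n_vals, size = 2L, signed = TRUE,
                   endian = "little") / 32768,
    "24" = {
      m <- matrix(as.numeric(data_raw[seq_len(3L * n_vals)]), nrow = 3L)
      x <- m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ]
      (x - 16777216 * (x >= 8388608)) / 8388608
    },
    "32" = readBin(data_raw, "integer", n_vals, size = 4L,
                   endian = "little") / 2147483648)
  nc <- max(1L, fmt$n_channels)
  if (nc > 1L) {
    n_frames <- n_vals %/% nc
    v <- colMeans(matrix(v[seq_len(n_frames * nc)], nrow = nc))
  }
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  audio_clip(v, fmt$sample_rate, source_id = source_id)
}

#' Write a clip as 16-bit PCM WAV
#'
#' @param clip an [audio_clip()]. Amplitudes outside `[-1, 1]` are clipped.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  q <- as.integer(pmax(-32768, pmin(32767, round(clip$samples * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(q)
  sr <- as.integer(round(clip$sample_rate))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(1L)               # PCM, mono
  w32(sr); w32(sr * 2L)          # byte rate
  w16(2L); w16(16L)              # block align, bits
  writeChar("data", con, eos = NULL); w32(data_bytes)
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}

#' Compute a magnitude spectrogram
#'
#' Short-time Fourier transform magnitude with explicit axis conventions:
#' frame `t` (1-based) covers samples `[(t-1)*hop, (t-1)*hop + window_length)`
#' and `time_axis` holds frame-center times in seconds. `freq_axis` is Hz per
#' bin, ascending, with `window_length/2 + 1` bins.
#'
#' Defaults (512-sample Hann window, 50% overlap) give about 11.6 ms / 86 Hz
#' resolution at 44.1 kHz — adequate to separate a 1000–6100 Hz song band.
#'
#' @param clip an [audio_clip()].
#' @param window_length analysis window in samples (>= 16).
#' @param hop hop size in samples (>= 1).
#' @param window_name one of `"hann"`, `"hamming"`, `"rectangular"`.
#' @return An object of class `spectrogram`.
#' @export
compute_spectrogram <- function(clip, window_length = 512L,
                                hop = window_length %/% 2L,
                                window_name = c("hann", "hamming", "rectangular")) {
  stopifnot(inherits(clip, "audio_clip"))
  window_name <- match.arg(window_name)
  window_length <- as.integer(window_length)
  hop <- as.integer(hop)
  if (window_length < 16L) stop("window_length must be >= 16 samples")
  if (hop < 1L) stop("hop must be >= 1 sample")
  n <- length(clip$samples)
  if (n < window_length) stop("clip is shorter than one analysis window")

  n_frames <- (n - window_length) %/% hop + 1L
  k <- seq_len(window_length) - 1L
  w <- switch(window_name,
    hann        = 0.5 - 0.5 * cos(2 * pi * k / window_length),
    hamming     = 0.54 - 0.46 * cos(2 * pi * k / window_length),
    rectangular = rep(1, window_length))
  idx <- outer(seq_len(window_length), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(clip$samples[idx], nrow = window_length) * w
  ft <- stats::mvfft(frames)
  nb <- window_length %/% 2L + 1L
  structure(
    list(magnitude = Mod(ft[seq_len(nb), , drop = FALSE]),
         freq_axis = (seq_len(nb) - 1L) * clip$sample_rate / window_length,
         time_axis = ((seq_len(n_frames) - 1L) * hop + window_length / 2) /
                     clip$sample_rate,
         window_length = window_length, hop = hop, window_name = window_name,
         sample_rate = clip$sample_rate, source_id = clip$source_id,
         clip_duration = clip$duration),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram '%s': %d bins x %d frames, %s %d/%d>\n",
              x$source_id, nrow(x$magnitude), ncol(x$magnitude),
              x$window_name, x$window_length, x$hop))
  invisible(x)
}
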