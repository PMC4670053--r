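#' Song template
#'
#' Parametric stand-in for a target song: an amplitude-modulated two-component
#' frequency sweep ("trill"). Realism is explicitly not the goal — the
#' statistical structure (band, duration, SNR, confounds) is what the
#' detector and classifier exercise. Target songs live in 0.5–5 s and
#' 1000–6100 Hz; distractor templates may sit anywhere.
#'
#' @param duration seconds, in `(0.05, 10]`.
#' @param freq_start,freq_end sweep endpoints in Hz (> 0).
#' @param trill_rate amplitude-modulation rate in Hz (0 = plain sweep).
#' @param amplitude linear peak gain.
#' @return Object of class `song_template`.
#' @export
song_template <- function(duration, freq_start, freq_end, trill_rate = 15,
                          amplitude = 1) {
  if (!(duration > 0.05 && duration <= 10)) stop("duration out of range")
  if (freq_start <= 0 || freq_end <= 0) stop("frequencies must be positive")
  if (trill_rate < 0) stop("trill_rate must be >= 0")
  if (amplitude <= 0) stop("amplitude must be positive")
  structure(list(duration = duration, freq_start = freq_start,
                 freq_end = freq_end, trill_rate = trill_rate,
                 amplitude = amplitude),
            class = "song_template")
}

#' Synthesize one song
#'
#' A linear frequency sweep plus a weaker constant mid-band component, both
#' amplitude-modulated at `trill_rate` and shaped by a raised-cosine
#' onset/offset; energy is confined to
#' `[min(freq_start, freq_end) - 100, max(...) + 100]` Hz.
#'
#' @param template a [song_template()].
#' @param sample_rate Hz.
#' @return An [audio_clip()] of the template duration, peak-normalized to the
#'   template amplitude.
#' @export
synth_song <- function(template, sample_rate) {
  stopifnot(inherits(template, "song_template"))
  n <- max(2L, round(template$duration * sample_rate))
  t <- (seq_len(n) - 1L) / sample_rate
  f0 <- template$freq_start; f1 <- template$freq_end
  dur <- template$duration
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2)
  x <- sin(phase) + 0.35 * sin(2 * pi * ((f0 + f1) / 2) * t)
  if (template$trill_rate > 0)
    x <- x * (0.65 + 0.35 * cos(2 * pi * template$trill_rate * t))
  ramp <- max(0.01, min(0.05 * dur, 0.05))
  nr <- max(1L, round(ramp * sample_rate))
  env <- rep(1, n)
  up <- seq_len(min(nr, n))
  env[up] <- 0.5 - 0.5 * cos(pi * (up - 1L) / nr)
  env[n + 1L - up] <- pmin(env[n + 1L - up], 0.5 - 0.5 * cos(pi * (up - 1L) / nr))
  x <- x * env
  x <- x / max(abs(x)) * template$amplitude
  audio_clip(x, sample_rate, source_id = "synth_song")
}

#' Soundscape specification
#'
#' The stated world the generator emulates: target songs 0.5–5 s long in a
#' 1000–6100 Hz band over broadband background noise, with in-band distractor
#' vocalizations and (optionally) a constant narrowband "cricket" confound
#' overlapping the target band. Degradation classes mirror the four-class
#' annotation scheme: class 3 = clean song, class 2 = partial distractor
#' overlap, class 1 = heavy overlap; the default mix (0.50/0.34/0.16) follows
#' the observed field split.
#'
#' @param duration soundscape length in seconds.
#' @param sample_rate Hz (field default 44100).
#' @param n_target_songs number of target songs to place.
#' @param target_snr_db in-band amplitude SNR of each song, dB.
#' @param distractors list of `list(template =, count =)` entries.
#' @param cricket_band optional `list(center_hz =, bandwidth_hz =, level_db =)`;
#'   `level_db` is the cricket RMS relative to the background noise RMS
#'   inside the 1000–6100 Hz target band.
#' @param noise_level standard deviation of the broadband white noise.
#' @param degradation_class_mix fractions for classes 1/2/3; must sum to 1.
#' @param seed integer seed; same seed gives bit-identical output.
#' @param source_id recording identifier.
#' @return Object of class `soundscape_spec`.
#' @export
soundscape_spec <- function(duration = 90, sample_rate = 44100,
                            n_target_songs = 14, target_snr_db = 25,
                            distractors = default_distractors(),
                            cricket_band = NULL, noise_level = 0.01,
                            degradation_class_mix = c(class1 = 0.50,
                                                      class2 = 0.34,
                                                      class3 = 0.16),
                            seed = 1L, source_id = NULL) {
  if (abs(sum(degradation_class_mix) - 1) > 1e-8)
    stop("degradation_class_mix must sum to 1")
  if (duration <= 0 || sample_rate <= 0) stop("invalid duration/sample_rate")
  if (n_target_songs < 0) stop("n_target_songs must be >= 0")
  if (noise_level <= 0) stop("noise_level must be positive")
  if (is.null(source_id)) source_id <- sprintf("synth_%d", as.integer(seed))
  structure(list(duration = duration, sample_rate = sample_rate,
                 n_target_songs = as.integer(n_target_songs),
                 target_snr_db = target_snr_db, distractors = distractors,
                 cricket_band = cricket_band, noise_level = noise_level,
                 degradation_class_mix = degradation_class_mix,
                 seed = as.integer(seed), source_id = source_id),
            class = "soundscape_spec")
}

#' Default distractor set
#'
#' A heterogeneous family of in-band non-target vocalizations: per event, an
#' un-trilled sweep with random duration (0.8–2.2 s), random band segment
#' inside 1500–4000 Hz, random direction, and random relative level (0.5–1.2
#' of the target-song gain). The energy detector picks these up and they
#' become class-0 training material with realistic within-class variability
#' — the field's class 0 was "other species and noises", not one fixed sound
#' — while remaining distinguishable in principle from the target song
#' (always trilled, reaching 2500–5800 Hz), as another species' call is.
#' Pass explicit `list(template =, count =)` entries instead for a
#' deterministic distractor population.
#'
#' @param count how many distractors to place.
#' @return A list usable as `distractors` in [soundscape_spec()].
#' @export
default_distractors <- function(count = 6L) {
  list(list(family = "random_sweep", count = as.integer(count)))
}

# One random distractor/masker template (caller provides seeded RNG state).
# The family is heterogeneous but distinguishable from the target song the
# way another species' call is: un-trilled and confined below ~4 kHz, while
# target songs are always trilled and reach into 2500-5800 Hz.
random_sweep_template <- function(amplitude = stats::runif(1, 0.5, 1.2)) {
  dur <- stats::runif(1, 0.8, 2.2)
  f0 <- stats::runif(1, 1500, 2800)
  f1 <- f0 + stats::runif(1, 600, 1200)
  if (stats::runif(1) < 0.5) { tmp <- f0; f0 <- f1; f1 <- tmp }
  song_template(dur, f0, f1, trill_rate = 0, amplitude = amplitude)
}

# Background-noise RMS inside [lo, hi] for white noise of sd sigma (flat PSD).
band_noise_rms <- function(sigma, lo, hi, sample_rate) {
  sigma * sqrt((hi - lo) / (sample_rate / 2))
}

# Narrowband noise: FFT brick-wall bandpass of white noise, scaled to rms.
narrowband_noise <- function(n, sample_rate, center, bandwidth, rms) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- (seq_len(n) - 1L) * sample_rate / n
  freqs <- pmin(freqs, sample_rate - freqs)  # two-sided
  keep <- freqs >= (center - bandwidth / 2) & freqs <= (center + bandwidth / 2)
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  x / sqrt(mean(x^2)) * rms
}

#' Synthesize a soundscape with known ground truth
#'
#' Places `n_target_songs` at non-overlapping random times (minimum gap
#' 0.3 s between all placed events), injects distractors, the optional
#' cricket band and white background noise, and returns the waveform together
#' with a truth selection table recording each target song's time-frequency
#' box and degradation class. Deterministic given `spec$seed`.
#'
#' Degradation class is a selection-quality proxy (in the field it tracks
#' distance and acoustic clutter), realized by two coupled mechanisms:
#' attenuation of the song itself (class 1 at 0.5x the target gain, class 2
#' at 0.75x, class 3 at 1x) and an overlaid masking sweep drawn from the
#' same distractor family that produces class-0 candidates (class 1: 1–2x
#' the song level over 80% of it; class 2: 0.5x over 40%; class 3:
#' untouched) — so a class-1 candidate genuinely is a faint song mixed into
#' a class-0-like box, as the annotation scheme describes. Class counts
#' follow largest-remainder rounding of `degradation_class_mix`.
#'
#' @param spec a [soundscape_spec()].
#' @return List with `clip` (an [audio_clip()]) and `truth` (a selection
#'   data frame with `class_label` in 1–3).
#' @export
synth_soundscape <- function(spec) {
  stopifnot(inherits(spec, "soundscape_spec"))
  sr <- spec$sample_rate
  n <- round(spec$duration * sr)
  with_seed(spec$seed, {
    x <- stats::rnorm(n, 0, spec$noise_level)
    nb_rms <- band_noise_rms(spec$noise_level, 1000, 6100, sr)

    # draw target templates
    n_t <- spec$n_target_songs
    targets <- lapply(seq_len(n_t), function(i) {
      dur <- stats::runif(1, 0.8, 2.2)
      f0 <- stats::runif(1, 2500, 4300)
      bw <- stats::runif(1, 800, 1500)
      song_template(dur, f0, min(f0 + bw, 5800),
                    trill_rate = stats::runif(1, 10, 20))
    })
    dist_templates <- list()
    for (d in spec$distractors) {
      dist_templates <- c(dist_templates, if (!is.null(d$template))
        rep(list(d$template), d$count)
        else lapply(seq_len(d$count), function(i) random_sweep_template()))
    }
    events <- c(targets, dist_templates)
    k <- length(events)

    starts <- numeric(0)
    if (k > 0L) {
      # uniform non-overlapping placement with a fixed guard gap
      gap <- 0.3
      durs <- vapply(events, `[[`, numeric(1), "duration")
      ord <- sample.int(k)
      durs_o <- durs[ord]
      free <- spec$duration - sum(durs_o) - gap * (k + 1)
      if (free < 0) stop("songs do not fit in the soundscape duration")
      u <- sort(stats::runif(k, 0, free))
      starts_o <- u + gap + cumsum(c(0, utils::head(durs_o, -1) + gap))
      starts <- numeric(k)
      starts[ord] <- starts_o
    }

    # degradation classes for targets (order randomized)
    counts <- largest_remainder(n_t, spec$degradation_class_mix)
    cls <- rep(c(1L, 2L, 3L), counts)
    if (n_t > 0L) cls <- cls[sample.int(n_t)]

    class_gain <- c(0.5, 0.75, 1)  # selection-quality proxy, classes 1..3
    truth <- list()
    for (i in seq_len(k)) {
      tpl <- events[[i]]
      clip_i <- synth_song(tpl, sr)
      s <- clip_i$samples
      # template amplitude acts as a relative gain on top of the target SNR
      gain <- nb_rms * 10^(spec$target_snr_db / 20) / sqrt(mean(s^2)) *
        tpl$amplitude
      if (i <= n_t) gain <- gain * class_gain[cls[i]]
      s <- s * gain
      i0 <- round(starts[i] * sr) + 1L
      seg <- i0:(i0 + length(s) - 1L)
      x[seg] <- x[seg] + s

      if (i <= n_t) {
        # degradation masker inside the song interval
        cl <- cls[i]
        if (cl < 3L) {
          # overlap with a sound from the same family the class-0 candidates
          # come from: heavy and at least song-loud for class 1, lighter for
          # class 2
          cover <- if (cl == 1L) 0.8 else 0.4
          rel_amp <- if (cl == 1L) stats::runif(1, 1, 2) else 0.5
          mtpl <- random_sweep_template(amplitude = 1)
          mtpl$duration <- max(0.1, cover * tpl$duration)
          m <- synth_song(mtpl, sr)$samples
          song_rms <- sqrt(mean(s^2))
          m <- m / sqrt(mean(m^2)) * song_rms * rel_amp
          off <- round((tpl$duration - mtpl$duration) / 2 * sr)
          mseg <- (i0 + off):(i0 + off + length(m) - 1L)
          x[mseg] <- x[mseg] + m
        }
        flo <- min(tpl$freq_start, tpl$freq_end)
        fhi <- max(tpl$freq_start, tpl$freq_end)
        truth[[length(truth) + 1L]] <- data.frame(
          begin_time = starts[i], end_time = starts[i] + tpl$duration,
          low_freq = max(0, flo - 100), high_freq = fhi + 100,
          class_label = cls[i])
      }
    }

    if (!is.null(spec$cricket_band)) {
      cb <- spec$cricket_band
      x <- x + narrowband_noise(n, sr, cb$center_hz, cb$bandwidth_hz,
                                nb_rms * 10^(cb$level_db / 20))
    }

    truth_df <- if (length(truth) > 0L) {
      df <- do.call(rbind, truth)
      df <- df[order(df$begin_time), , drop = FALSE]
      selection_table(selection_id = seq_len(nrow(df)),
                      source_id = spec$source_id,
                      begin_time = df$begin_time, end_time = df$end_time,
                      low_freq = df$low_freq, high_freq = df$high_freq,
                      class_label = df$class_label)
    } else empty_selection_table(spec$source_id)

    list(clip = audio_clip(x, sr, source_id = spec$source_id),
         truth = truth_df)
  })
}

#' Reference desk-scale soundscape
#'
#' The fixed synthetic world used by the package's end-to-end evaluation: a
#' 90 s soundscape at 22.05 kHz (desk-scale; the band tops out at 6.1 kHz so
#' Nyquist is ample) with 14 target songs at 25 dB in-band SNR, 6 in-band
#' distractor sweeps, the default 0.50/0.34/0.16 degradation mix, and —
#' when `cricket = TRUE` — a constant narrowband cricket confound at
#' 4000 +/- 200 Hz, 10 dB over the background in-band RMS (about 11x the
#' background level per bin, i.e., clearly the loudest constant element).
#' Because the cricket is constant it inflates the detector's noise estimate
#' (about +5 dB on the band-summed threshold here), so it contaminates boxes
#' and features while detection keeps functioning — the regime the confound
#' emulates: in the field the detector still produced thousands of
#' candidates and the errors appeared at the identification stage. A cricket
#' as loud as the songs themselves (25 dB) suppresses every candidate
#' outright, and 15 dB already halves recall and wipes out the clean song
#' classes.
#'
#' @param seed integer seed (one soundscape per seed).
#' @param cricket enable the cricket-band confound.
#' @return A [soundscape_spec()].
#' @export
reference_soundscape_spec <- function(seed, cricket = FALSE) {
  soundscape_spec(
    duration = 90, sample_rate = 22050, n_target_songs = 14L,
    target_snr_db = 25, distractors = default_distractors(6L),
    cricket_band = if (cricket)
      list(center_hz = 4000, bandwidth_hz = 400, level_db = 10),
    noise_level = 0.01, seed = seed,
    source_id = sprintf("ref_%s_%d", if (cricket) "cricket" else "easy",
                        as.integer(seed)))
}

#' Build a labeled training corpus from synthetic soundscapes
#'
#' End-to-end emulation of the training phase on data with known truth: each
#' soundscape is synthesized, the energy detector is run, candidates are
#' matched to the truth table (temporal overlap at least
#' `overlap_threshold`), and labels are assigned the way a manual annotator
#' grades *selections*: a matched candidate gets the song's degradation
#' class downgraded by its own box quality — overlap of at least 0.9 of the
#' song keeps the class, at least 0.7 caps it at 2, anything down to
#' `overlap_threshold` caps it at 1 (a clipped box over a clean song is
#' still a "bad selection") — and unmatched candidates get class 0. Features
#' are then measured on every candidate.
#'
#' @param specs list of [soundscape_spec()]s.
#' @param detector_cfg a [detector_config()].
#' @param window_length,hop,window_name spectrogram parameters.
#' @param overlap_threshold matching threshold (default 0.5).
#' @return List: `features` (measurement table with `class_label`), `labels`
#'   (binary factor), `classes` (0–3 vector), `truth` (list of truth tables),
#'   `detections` (list of candidate tables), `scores` (list of
#'   [match_detections()] results).
#' @export
make_training_corpus <- function(specs, detector_cfg = detector_config(),
                                 window_length = 512L,
                                 hop = window_length %/% 2L,
                                 window_name = "hann",
                                 overlap_threshold = 0.5) {
  feats <- list(); truths <- list(); dets <- list(); scores <- list()
  for (i in seq_along(specs)) {
    ss <- synth_soundscape(specs[[i]])
    spec_gram <- compute_spectrogram(ss$clip, window_length = window_length,
                                     hop = hop, window_name = window_name)
    cand <- detect_candidates(spec_gram, detector_cfg)
    sc <- match_detections(cand, ss$truth,
                           overlap_threshold = overlap_threshold)
    cand$class_label <- rep(0L, nrow(cand))
    if (nrow(sc$pairs) > 0L) {
      quality <- ifelse(sc$pairs$overlap >= 0.9, 3L,
                        ifelse(sc$pairs$overlap >= 0.7, 2L, 1L))
      cand$class_label[sc$pairs$det] <- pmin(sc$pairs$class_label, quality)
    }
    m <- suppressMessages(measure_all(spec_gram, cand))
    feats[[i]] <- m
    truths[[i]] <- ss$truth
    dets[[i]] <- cand
    scores[[i]] <- sc
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  if (is.null(features$class_label))
    features$class_label <- integer(nrow(features))
  bl <- binarize_labels(features)
  list(features = features, labels = bl$binary,
       classes = features$class_label, truth = truths, detections = dets,
       scores = scores)
}
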