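---
title: "Detecting a target species' song: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a target species' song: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songsvm)
```

## The problem and the pipeline

Passive acoustic monitoring leaves a manager with hundreds of hours of field
recordings and the question "is the species here, and roughly how abundant?".
`songsvm` implements a deliberately simple two-phase answer for a single
target species whose song occupies a known frequency band and duration range
(the motivating case: a Hawaiian honeycreeper singing 0.5–5 s songs between
1000 and 6100 Hz, recorded at 44.1 kHz by autonomous duty-cycled recorders).

**Training phase.** (I) A band-limited energy detector segments *candidate
songs*: spectrogram intervals whose in-band energy exceeds the estimated
background noise by an SNR threshold, within the band and duration window.
(II) A human annotates each candidate into four classes — 0: not the target;
1: target song poorly selected / heavily overlapped with other sounds;
2: some overlap; 3: clean — which binarize to absence (0) vs presence (1–3).
(III) Sixteen robust acoustic features are measured per candidate and a
binary RBF-kernel support vector machine is tuned over a decade grid of
(gamma, cost) and evaluated by repeated 70/30 stratified holdout using
balanced accuracy,

$$\mathrm{BAC} = \frac{P(A) + P(B)}{2} \times 100,$$

where \(P(A)\) and \(P(B)\) are the proportions of presence and absence
candidates classified correctly, plus the area under the ROC curve
(Mann–Whitney formulation, ties counted one half).

**Testing phase.** New recordings are scanned with the same detector, each
candidate is classified by the trained SVM, and the positives feed a presence
report (with a capped, score-ranked review table for manual spectrogram
confirmation — false positives are easy to recognize by eye) and a
calls-per-minute relative-abundance table. Sites are compared with Gaussian
linear mixed models (random intercept per recording point, with and without
a site fixed effect) fitted by maximum likelihood and compared by AIC, with
models within 2 AIC units treated as equally supported.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_freq`, `max_freq` | 1000, 6100 | Hz | the target song band (the source protocol states these two numbers with the labels swapped; the literal reading is an empty band, so they are used as min/max) |
| `min_duration`, `max_duration` | 0.5, 5 | s | the target song envelope |
| `snr_threshold` | 10 | dB (amplitude, `20*log10`) | detection margin over noise; tuned per deployment via `tune_detector()` |
| `noise_percentile`, `noise_block` | 0.5, 10 | –, s | per-bin order-statistic noise level over tumbling blocks; the median is robust to sparse song energy |
| `min_separation` | 0.1 | s | gaps shorter than this merge adjacent detections (trills pulse) |
| `min_occupancy` | 0.5 | – | fraction of above-threshold frames a detection (and each occupied bin) must reach |
| `window_length`, `hop` | 512, 256 | samples | Hann, 50% overlap: ~11.6 ms / 86 Hz at 44.1 kHz, adequate for a 5 kHz-wide band |
| SVM grid | \(10^{-10}\dots10^{10}\) | – | decade steps in gamma and cost, 441 pairs |
| `train_fraction`, `n_reps` | 0.7, 1000 | – | the published evaluation protocol |
| learning-curve fractions | 0.9 … 0.1 | – | the nine published subsampling levels |

The reference analysis protocol never states the spectrogram settings or
Raven's internal noise estimator; both are explicit, documented choices here
and exposed in the JSON run configuration.

## Numerical and procedural choices

* **Noise estimation** is the per-bin `noise_percentile` order statistic
  (inverted-ECDF percentile, `type = 1`) within consecutive
  `noise_block`-second blocks, the last partial block merging into its
  predecessor. A sliding window would be smoother but is ambiguous at edges
  and far more expensive; the tumbling-block estimator is deterministic,
  fast, and exactly reproducible by a brute-force oracle, which the test
  suite exploits.
* **Detection extent.** A frequency bin counts toward a detection's box only
  if it exceeds its own noise level in at least `min_occupancy` of the run's
  marked frames; a single noisy frame must not widen the box.
* **SNR is compared on amplitude** (`20*log10`), matching how field
  protocols quote detector thresholds.
* **Features are z-scored inside the classifier** (population SD, so
  duplicating rows cannot change the model), not in the measurement module —
  measured values stay physically interpretable. Zero-variance features are
  dropped and recorded on the model object. Whether the original analysis
  standardized is unstated; the RBF kernel is distance-based, so
  standardization is the safe default and can be disabled.
* **Hyperparameter tuning** defaults to 5-fold stratified cross-validation
  (`tuning_mode = "cv"`), because the original tune-on-all-data procedure
  leaks information; `tuning_mode = "paper"` reproduces that procedure for
  fidelity. Ties break toward smaller cost, then smaller gamma (prefer the
  smoother model).
* **Class weighting** defaults to `balanced` (each class's box constraint
  scaled by \(n/2n_k\)): field annotation sets are heavily
  absence-dominated, and BAC is the target metric.
* **The SVM solver** is an in-package sequential-minimal-optimization
  implementation (second-order working-set selection, stopping tolerance
  `1e-3`, iteration cap `200 n`), validated against an independent reference
  implementation on a frozen fixture. It is deterministic given the data.
* **Repeated holdout** derives an independent sub-seed per repetition, so
  increasing `n_reps` extends rather than reshuffles the sequence of splits;
  splits are stratified so both classes always appear in the validation set
  (plain random splits can make BAC undefined).
* **AUC scores** are the SVM's signed decision values; the original report
  does not say what score fed its ROC curve.
* **Degenerate inputs**: an all-silent selection box yields `NA` spectral
  features and the batch wrapper excludes (and counts) such rows; a scan
  with zero detections reports `precision = 0` with an explicit
  `precision_defined = FALSE` flag; single-class truth makes BAC/AUC error
  rather than return a misleading number.
* **Model files are JSON** with 17-significant-digit doubles — a text
  artifact that round-trips the decision function bit-identically.
* **Mixed models** are fitted by maximum likelihood (not REML) because the
  compared models differ in fixed effects and are ranked by AIC. The source
  analysis calls the same model LMM in one place and GLMM in another; the
  Gaussian LMM it describes is what is implemented.

## The synthetic world: what a green test does and does not establish

No field recordings are distributed with the original analysis, so the
package ships a soundscape generator with known ground truth
(`synth_soundscape()`, `make_training_corpus()`); every pipeline stage is
exercised against constructed truth rather than against the original data.

A target song is a two-component frequency-modulated sweep (2500–5800 Hz
segments), amplitude-modulated at the trill rate (depth 0.35) and confined
to its declared band (±100 Hz); a soundscape places a stated number of songs
at non-overlapping seeded random times (0.3 s guard gaps) over white
background noise, adds in-band distractor vocalizations, and optionally a
constant narrowband cricket confound inside the song band. Song gain is
calibrated so the in-band amplitude SNR matches `target_snr_db` within 1 dB
(a tested invariant).

The distractor family stands in for "other species and noises": per event an
un-trilled sweep with random duration, random band segment inside
1500–4000 Hz, random direction and 0.5–1.2 times the song gain —
heterogeneous, as a real background chorus is, yet distinguishable in
principle from the target song (always trilled, reaching higher), the way
the target species' "very characteristic" song was distinguishable in the
field. Degradation class is a *selection-quality* proxy, realized by two
coupled mechanisms: attenuation of the song itself (class 1 at 0.5×, class 2
at 0.75×, class 3 at 1× the target gain — class-1 songs are the faint,
distant ones) and an overlaid masker drawn from the same distractor family
(class 1: 1–2× the song level over 80% of it; class 2: 0.5× over 40%);
the default mix 0.50/0.34/0.16 (largest-remainder rounding) follows the
observed field split. When `make_training_corpus()` labels detected
candidates, a matched candidate gets the song's class *downgraded by its own
box quality* (overlap ≥ 0.9 keeps the class, ≥ 0.7 caps it at 2, less caps
it at 1), because the annotation scheme grades selections, not songs — a
clipped box over a clean song is still a "bad selection". The reference
evaluation corpus (`reference_soundscape_spec()`) runs at 22.05 kHz and 90 s
per soundscape purely for desk-scale runtime; the band tops out at 6.1 kHz.

The cricket confound's level is a deliberate choice: 10 dB over the in-band
background RMS. Because the cricket is constant, the detector's
block-percentile noise estimate absorbs it and the band-summed threshold
rises about 5 dB, so detection *degrades* (boxes and features are
contaminated, faint clean songs start to drop out) without being silenced.
At the songs' own level (25 dB) the cricket suppresses every candidate —
a jammer, not the documented regime in which the detector kept producing
thousands of candidates while *identification* became harder. Consistent
with the field protocol, a confounded deployment should re-run the
interactive detector calibration: tuning `snr_threshold`/`min_occupancy`
with `tune_detector()` on one labeled confounded soundscape restores
detection recall (0.42 → ~1.0 in the reference world) and leaves the
classification stage to absorb the confound — which is where the end-to-end
tests then observe the expected structure: balanced accuracy drops relative
to the clean world and the heavily-overlapped class 1 becomes the
least-accurate presence class.

What the generator does **not** emulate: real song repertoire variation,
reverberation and distance-dependent high-frequency loss, diurnal noise
nonstationarity, overlapping target songs, or recorder artifacts. A green
end-to-end test therefore establishes that the machinery — detection
geometry, labeling by truth overlap, feature measurement, tuning,
holdout arithmetic — behaves correctly under the stated statistical
structure, *not* that any particular field accuracy would be achieved; the
original headline numbers (BAC 86.5 ± 1.01, AUC 0.942) came from recordings
that are not available and are not reproduced here.

## Known limitations

* One species, binary decision; multispecies extension is out of scope.
* No resampling: the pipeline runs at the native rate, and the detector
  band must lie below Nyquist.
* The detector is energy-based: a loud constant confound inside the band
  raises the noise floor and masks faint songs (this is visible in the
  cricket corpus, where clean faint songs are the first casualties);
  template cross-correlation detectors degrade differently.
* Calls per minute is a *relative* index: comparable across sites surveyed
  identically, in the same season, with similar vegetation and confound
  structure — not an absolute density.
* The full kernel matrix is materialized during SVM training, so training
  sets beyond ~10⁴ rows are impractical (field-scale annotation sets are
  thousands of rows).
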