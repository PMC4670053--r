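Package: songsvm
Title: Band-Limited Energy Detection and Support Vector Classification of
    Animal Song in Passive Acoustic Recordings
Version: 0.1.0
Authors@R:
    person("Avian", "Acoustics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-phase pipeline for detecting a target species' song in
    long-duration field recordings. A band-limited energy detector segments
    candidate vocalizations from spectrograms by signal-to-noise ratio within
    a frequency band and duration window; robust acoustic features are
    measured on each candidate; a binary support vector machine with radial
    basis kernel separates target songs from other sounds. Includes balanced
    accuracy and ROC/AUC evaluation with repeated stratified holdout,
    learning curves, Raven-style selection-table interoperability, call-rate
    relative abundance summaries with mixed-model site comparison, and a
    synthetic soundscape generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
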