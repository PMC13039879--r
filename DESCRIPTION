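Package: oddpupil
Title: Trial-Level Pupillometry and ERP Analysis for Passive Auditory
    Oddball Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for concurrent pupillometry and EEG recorded
    during a passive auditory oddball task. Generates counterbalanced
    oddball task schedules, preprocesses sample-level pupil recordings
    (plausibility range filter, repeated dilation-speed median-absolute-
    deviation outlier rejection, blink detection with gap padding, linear
    interpolation, binocular averaging) into per-trial baseline pupil size
    (BPS) and stimulus-evoked pupillary response (SEPR), extracts
    trial-level mismatch negativity (MMN) and P3a amplitude and latency
    from epoched EEG with zero-phase Butterworth low-pass filtering, fits
    trial-level and aggregated linear mixed-effects models with marginal
    contrasts and Nakagawa R-squared, and runs Monte-Carlo power
    simulations for interaction effects. A synthetic-data generator
    emulates two-eye 300 Hz pupil traces and multichannel ERP epochs with
    a configurable group-by-stimulus-by-manipulation effect structure so
    every stage is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
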