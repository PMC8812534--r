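Package: eegitt
Title: Intent-to-Treat Analysis of Infant EEG Band Power in Randomized Cash-Transfer Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating intent-to-treat effects of a
    randomized unconditional cash-transfer intervention on infant
    resting-state EEG power. Simulates a multi-site randomized cohort with
    baseline covariates, attrition and raw 20-channel 500-Hz EEG recordings
    whose band power embeds configurable standardized treatment effects;
    preprocesses recordings (temporal-average re-reference, zero-phase
    band-pass filtering, epoching with amplitude-based artifact rejection);
    extracts single-hertz-bin spectra and theta/alpha/beta/gamma absolute
    and relative power at whole-scalp and regional level; fits ordinary
    least squares with site fixed effects, baseline covariates,
    heteroskedasticity-robust standard errors and control-group
    standardized effect sizes; and adjusts families of outcomes with
    Westfall-Young free stepdown resampling for family-wise error control.
    Recordings round-trip through the European Data Format (EDF).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    sandwich
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
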