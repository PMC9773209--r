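Package: speechrestore
Title: Interrupted-Speech Stimulus Construction, Transcript Autoscoring, and
    Cognitive-Linguistic Analysis of Perceptual Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies of the perceptual restoration of missing
    speech. Builds interrupted-speech stimuli by square-wave gating of
    sentence audio (silent-gap and speech-shaped noise-burst variants with
    cosine ramps, RMS calibration, and configurable SNR), autoscores typed
    transcripts against per-sentence keyword lists under strict
    spelling-tolerance rules, scores standard cognitive and linguistic tasks
    (reading span, digit span, Stroop, flanker, LexTALE) from trial-level
    logs, and runs the accompanying statistical pipeline: 3xIQR outlier
    fencing, descriptives, Levene and Welch one-way tests,
    Benjamini-Hochberg pairwise comparisons, Pearson correlation screens,
    normalized-predictor regression with purposeful selection and
    diagnostics, and noncentral-F power analysis. A synthetic-data module
    generates speech-like audio and simulated cohorts with known ground
    truth so the whole pipeline is testable without access to participant
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    igraph,
    lmtest,
    MASS,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    e1071,
    jsonlite
Config/testthat/edition: 3
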