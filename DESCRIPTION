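Package: streamgbm
Title: Gradient-Boosted Analysis of Auditory Go/No-Go Word-Stream Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of Go/No-Go auditory word-stream
    psychophysics at the single-trial level. Provides a parametric task and
    observer simulator (word streams with pitch roving, per-token false-alarm
    hazards, injectable talker/F0/streaming effects), signal-detection
    metrics, gradient-boosted outcome and reaction-time models with
    cross-validated balanced accuracy and shuffled-label noise floors,
    exact Shapley-value feature attribution with a brute-force oracle,
    permutation importance, a word-frequency flattening resampler for
    per-word release-time attribution, cochleagram and envelope based
    acoustic similarity scoring, and mixed-effects and least-squares
    baselines over the same feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite,
    lme4,
    lmerTest,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
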