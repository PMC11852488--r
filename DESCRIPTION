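Package: eegemotion
Title: EEG-Based Emotion Classification and Safety-Behavior Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic re-implementation of an EEG
    emotion-recognition and safety-behavior analysis pipeline. Generates
    seeded 14-channel scalp EEG with controllable per-band spectral and
    complexity signatures for three emotional states (neutral, fear,
    anger), conditions it with zero-phase FIR band-pass and notch
    filtering, fixed 1-s epoching and threshold artifact rejection,
    extracts sample-entropy and band power-spectral-density features on
    temporal channels, and classifies emotional state per frequency band
    with a k-nearest-neighbor model evaluated by confusion matrices,
    per-class true-positive rates and one-vs-rest ROC curves. A companion
    behavioral arm simulates hazard-identification and risk-assessment
    trial tables and analyses them with one-way and 3x2 factorial ANOVA
    (simple effects, eta-squared), summary-statistics ANOVA audits, and
    multiple linear regression with variance-inflation-factor
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    withr
Config/testthat/edition: 3
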