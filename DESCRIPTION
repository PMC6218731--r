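Package: ppgbp
Title: Cuffless Blood Pressure Estimation from Photoplethysmogram Pulse Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating systolic and diastolic blood pressure from
    fingertip photoplethysmogram (PPG) waveforms alone, without an ECG or a
    pressure cuff.  The package covers the full pipeline: a seeded synthetic
    PPG generator with known ground-truth blood pressure, plain-text waveform
    and manifest input/output, rule-based signal-quality screening,
    Savitzky-Golay smoothing with baseline-wander removal and two-dimensional
    pulse normalization, extraction of five pulse-morphology features (area,
    rising time and fractional widths), variance-inflation-factor feature
    selection, three regression learners (multiple linear regression, linear
    epsilon-insensitive support vector regression and a CART regression tree),
    and k-fold cross-validated evaluation with per-case aggregation,
    blood-pressure-category stratification, Bland-Altman limits of agreement
    and an ISO 81060-style accuracy verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
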