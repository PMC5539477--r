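Package: hrvee
Title: Heart-Rate-Variability-Aided Activity Recognition and Energy-Expenditure Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing wearable-sensor recordings of single-lead ECG and a
    wrist-worn tri-axial accelerometer. The package extracts 31 heart-rate-variability
    (HRV) parameters (time-, frequency- and nonlinear-domain) per one-minute window and
    four accelerometer features per two-second window, classifies ambulatory activities
    (sitting, standing, walking, ascending, running) under leave-one-subject-out
    cross-validation with Mann-Whitney-based HRV feature selection, and estimates
    per-minute energy expenditure (kcal/min) with single and activity-specific linear
    regression models with and without HRV predictors. A synthetic-data generator
    emulates a 13-subject, six-activity laboratory protocol (ECG at 256 Hz,
    accelerometer at 128 Hz, per-minute reference energy expenditure) so that every
    stage of the analysis is testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
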