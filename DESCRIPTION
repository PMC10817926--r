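Package: fluidresp
Title: Fluid Responsiveness Prediction from Arterial Pressure Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts whether a fluid bolus will raise cardiac stroke volume by
    at least 15% using only features of the arterial blood pressure waveform,
    and benchmarks the machine-learning classifier against pulse pressure
    variation. Includes the full pipeline: a seeded synthetic hemodynamics
    simulator (multi-pig shock cohorts with respiratory modulation and planted
    fiducials), waveform preprocessing (decimation and Savitzky-Golay
    smoothing), beat fiducial detection (systolic peak, diastolic foot,
    dicrotic notch), a 50-feature per-bolus registry, stroke-volume labeling,
    pig-level stratified train/test splitting and cross-validation, four
    feature-selection methods with a consensus rule, classifier training
    (random forest, logistic regression, SVM, gradient boosting), and holdout
    evaluation with threshold sweeps, calibration curves and error analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    e1071,
    glmnet,
    xgboost,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
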