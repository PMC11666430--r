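Package: psaiiscreen
Title: Serum-Based Screening for Psoriatic Arthritis with Composite
    Inflammation Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of the Psoriatic Arthritis
    Inflammation Index (PSAII) and eight published composite inflammation
    indices for screening psoriatic arthritis among psoriasis patients.
    Provides synthetic cohort generation from published per-group summary
    statistics, chained random-forest imputation, min-max normalization
    with train/apply separation, univariate AUC and LASSO feature
    selection, a five-learner cross-validated benchmark, ROC/cutoff/
    calibration/decision-curve evaluation, restricted-cubic-spline
    dose-response analysis, and a combined PSAII+ToPAS triage rule.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    glmnet,
    randomForest,
    xgboost,
    nnet,
    caret,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
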