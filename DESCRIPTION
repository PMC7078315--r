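Package: markertrend
Title: Longitudinal Multimarker Trend Models for Early Cancer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating longitudinal multimarker
    classification models from serial serum biomarker measurements, as used in
    annual ovarian cancer screening. Serial per-marker trajectories are collapsed
    into scalar trend indices (mean derivative, area under the series,
    coefficient of variation, centre of mass, final value), candidate predictors
    are nominated by a five-criterion selection ensemble (AIC stepwise, lasso
    first-lambda rule, bootstrap lasso inclusion frequency, random-forest
    permutation and Gini importances), all logistic models with up to three
    features are fitted and ranked by leave-one-out cross-validation, and
    performance is summarised as sensitivity at fixed specificity with
    stratified-bootstrap confidence intervals, DeLong AUC, exact one-tailed
    McNemar comparison against a single-marker cut-off reference,
    Hosmer-Lemeshow calibration, and loess-based lead-time estimation.
    A synthetic nested case-control cohort generator with change-point marker
    kinetics provides ground-truthed data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    glmnet,
    randomForest,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
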