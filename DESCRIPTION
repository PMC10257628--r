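Package: noshowce
Title: Cost-Effectiveness-Driven Prediction of Outpatient No-Shows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts which scheduled outpatient appointments are likely to
    be missed and turns the predictions into actionable, budget-aware call
    lists. Implements confusion-matrix-derived cost-effectiveness metrics
    (proportion of actions P_C, no-show reduction P_R, and the composite
    metrics m1 = P_R/P_C and m2 = P_R*(1-P_C)), per-specialty model
    selection over a roster of imbalanced-learning classifiers with
    classification-threshold tuning, descending-risk ranking for
    deployment, a randomized reminder-trial evaluator, and a synthetic
    longitudinal appointment-schedule generator for end-to-end testing
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    rpart,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
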