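Package: adprogress
Title: Integrated Causal and Machine-Learning Prediction of Progression
    from Depression to Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts progression from major depressive disorder (MDD) to
    Alzheimer's disease (AD) in longitudinal claims data by stacking two
    base learners: a marginal structural model fitted by weighted least
    squares with stabilized inverse-probability-of-treatment weights that
    control for time-varying confounding, and a multilayer perceptron
    trained with L-BFGS. Their predicted probabilities feed a
    gradient-boosted meta-classifier (the integrated predictive model).
    Includes a seeded synthetic Medicare-style claims simulator with ICD-9
    and ICD-10 coding, an ICD-based cohort builder with descriptive
    statistics, a full ROC/AUC evaluation panel with bootstrap confidence
    intervals, and a sensitivity-analysis protocol that masks 40% of
    predictor cells and multiply imputes them with a multivariate-normal
    Gibbs sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    lmtest,
    MASS,
    pROC,
    sandwich,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
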