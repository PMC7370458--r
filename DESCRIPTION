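Package: qolmap
Title: Mapping EORTC QLQ-C30 Responses onto EQ-5D-3L Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores EORTC QLQ-C30 v3.0 questionnaires and EQ-5D-3L health
    states under pluggable country value sets, and estimates utility
    mapping (cross-walk) algorithms for cost-effectiveness analysis.
    Implements six mapping-model families: random-intercept linear models
    on scale scores, item scores or item-level dummies (with cluster-robust
    inference, backward selection and removal of non-logical coefficients),
    response mapping via ordered logit on the five EQ-5D domains, beta
    regression on transformed disutilities, and a separate-equations
    mixture. Includes a calibrated synthetic paired-questionnaire cohort
    generator, 5-fold cross-validated performance metrics (RMSE, MAE,
    Spearman correlation, t-test), evaluation on incomplete questionnaires
    under the half-completion rule, and a simplified two-arm
    cost-effectiveness layer with method-of-moments probabilistic
    sensitivity analysis of the ICER.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    mgcv,
    MASS,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
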