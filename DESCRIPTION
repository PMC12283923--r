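Package: causalor
Title: Marginal Odds-Ratio Causal Inference for Binary Exposures in
    Observational Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the marginal odds ratio of a binary exposure on a
    binary outcome in an observational cohort by G-computation, inverse
    probability of treatment weighting (IPTW), targeted maximum likelihood
    estimation (TMLE), and TMLE with a cross-validated super-learner
    ensemble.  Provides percentile-bootstrap and efficient-influence-curve
    confidence intervals, a calibrated synthetic cohort generator with a
    known-truth oracle, descriptive cohort statistics with a
    normality-gated test battery and Benjamini-Hochberg correction,
    positivity and covariate-balance diagnostics (effective sample size,
    standardized mean differences), and a confounding-function sensitivity
    analysis for unmeasured confounding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    kernlab,
    class,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    pracma
Config/testthat/edition: 3
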