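Package: codbayes
Title: Bayesian Estimation of the Discrete Coefficient of Determination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimators of the discrete coefficient of determination (CoD)
    between binary predictor variables and a binary target, under the
    Beta-Dirichlet conjugate model: the exact minimum mean-square error
    (MMSE) posterior-expectation estimator, the optimal Bayesian predictor
    (OBP) estimator, and classical nonparametric baselines (resubstitution,
    leave-one-out, 0.632 bootstrap, repeated twofold cross-validation).
    Includes exact fixed-parameter bias/variance/RMS formulas for the OBP
    estimator, Monte-Carlo benchmarking of global and fixed-parameter
    accuracy, a power-series implementation of the incomplete Beta function,
    and a two-step empirical-Bayes model-selection procedure for inferring
    Boolean gene-regulatory networks from binarized expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
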