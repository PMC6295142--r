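Package: bmikin
Title: Cross-Generation BMI Prediction with Multiple Imputation and Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for predicting a child's body
    mass index (BMI) from the BMI of parents and grandparents in three-generation
    family cohorts with heavy, missing-completely-at-random missingness.
    Provides a synthetic family-BMI generator with configurable linear,
    smooth-nonlinear and interaction effects; multiple imputation by iterative
    (regularized) principal-component analysis and by chained equations with
    Bayesian linear regression (NORM) or predictive mean matching (PMM);
    prediction by linear models, small sigmoidal feed-forward neural networks
    trained by full-batch backpropagation, and additive backfitting smoothers;
    leave-one-out cross-validation with minimum-over-repetitions errors,
    Rubin's-rules pooling of coefficients across imputed datasets, and a
    pattern-stratified "reduction method" gold standard that fits one model per
    missingness pattern without imputing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
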