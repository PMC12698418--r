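Package: collagensig
Title: Collagen Signature Modeling from Second-Harmonic-Generation Style Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies collagen architecture in second-harmonic-generation
    (SHG) style grayscale microscopy images through a fixed vocabulary of 142
    morphological, intensity, and textural features, builds a LASSO-derived
    scalar collagen signature, and integrates the signature with
    clinicopathological covariates into a logistic nomogram for predicting
    central lymph node metastasis. Includes a synthetic SHG image and cohort
    simulator with known ground truth, fiber tracing and crosslink detection
    on skeletonized collagen masks, gray-level co-occurrence matrix and Gabor
    filter bank texture features, train-only feature standardization,
    cross-validated L1-penalized logistic feature selection, nomogram
    construction, and evaluation by ROC/AUC, DeLong comparison, bootstrap
    confidence intervals, calibration curves, and decision curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    EBImage,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
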