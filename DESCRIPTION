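Package: sersnet
Title: Serum SERS Spectral Classification with a 1D Convolutional Network
    and Grad-CAM Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for label-free serum surface-enhanced
    Raman scattering (SERS) diagnostics: simulation of multi-group serum
    SERS spectra with a literature-derived prominent-peak lexicon,
    Savitzky-Golay smoothing, iterative fifth-order polynomial baseline
    removal, min-max normalization, sample-level five-fold partitioning
    with within-class convex-combination augmentation, a four-block
    one-dimensional convolutional neural network trained with rectified
    Adam and class-weighted cross-entropy, multi-metric evaluation with
    one-vs-rest ROC/AUC, chemometric PCA-LDA and PCA-SVM baselines, and
    quantitative spectral interpretation by gradient-weighted class
    activation mapping with per-peak full-width-at-half-maximum area
    contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    MASS,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
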