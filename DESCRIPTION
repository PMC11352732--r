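Package: met2star
Title: T2* Mapping and BOLD Sensitivity Analysis for Multi-Echo fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative T2* mapping from multi-echo gradient-echo fMRI and a
    BOLD-sensitivity evaluation suite. Implements the mono-exponential
    multi-echo signal model, voxel-wise log-linear fitting (LLF), T2*-weighted
    echo combination, and a synthetic-data-trained convolutional estimator
    (a 4-level U-net trained purely on procedurally generated parametric
    phantoms with Rician noise) that performs slice-by-slice T2* mapping.
    Ships a multi-echo task-fMRI simulator with known ground-truth BOLD
    effects, and first-level analysis tools: polynomial detrending, Gaussian
    smoothing, GLM with HRF-convolved block regressors, temporal SNR,
    percentage signal change, functional contrast, family-wise-error masks,
    and paired effect-size comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
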