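Package: rvshape
Title: Statistical Shape Analysis of the Right Ventricle in Tricuspid
    Regurgitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end particle-based statistical shape analysis of right
    ventricular (RV) endocardial segmentations, aimed at characterising the
    RV remodelling that accompanies tricuspid regurgitation (TR). Provides a
    synthetic cohort generator of star-shaped RV-like surfaces with known
    group deformations and ground-truth correspondence; segmentation
    preprocessing (isotropic resampling, rigid alignment, signed distance
    transforms); particle-based correspondence optimization; a PCA shape
    space; TR classification with Borderline-SMOTE balancing and lasso
    stability feature selection; linear-discrimination shape scores with
    Gaussian density fits; and per-point Hotelling T-squared significance
    maps with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    RNifti,
    jsonlite,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
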