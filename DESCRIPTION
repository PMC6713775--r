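Package: xerodelta
Title: Delta-Radiomics NTCP Modelling of Radiation-Induced Xerostomia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal (delta-) radiomics analysis of parotid-gland
    changes seen on weekly CT during head-and-neck radiotherapy, and
    logistic NTCP (normal tissue complication probability) modelling of
    late patient-rated xerostomia. Provides a synthetic longitudinal
    cohort generator (shrinking parotid-like ROIs with controllable
    CT-like texture and outcomes drawn from a known logistic truth),
    IBSI-style geometric, first-order and texture feature extraction
    (GLCM, GLRLM, GLSZM, NGTDM) from 3D volumes with anisotropic voxel
    spacing, weekly delta-feature construction with asymmetric baselines,
    bootstrapped correlation-prefilter + forward-selection variable
    selection, multivariable logistic NTCP models with odds ratios and
    likelihood-ratio tests, and bootstrap internal validation with
    optimism-corrected performance and calibration-slope-shrunken
    coefficients.
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
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
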