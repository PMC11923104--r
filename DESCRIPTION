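Package: StromaSurv
Type: Package
Title: Tumor, Stroma and Lymphocyte Quantification and Prognostic
    Stratification for H&E Histology
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tile-based three-class semantic segmentation of
    hematoxylin-and-eosin histology into tumor, stroma and lymphocyte
    regions with a valid-convolution U-Net (overlapping-tile inference,
    Macenko stain normalization), slide-level quantification of stroma,
    lymphocyte and tumor area fractions (SIP/LIP/TIP), optimal survival
    cutpoints (maximally selected rank statistics and an exhaustive
    two-threshold three-group search), combined risk grouping, and
    Kaplan-Meier / Cox proportional-hazards survival analysis.  Includes
    generators for synthetic H&E-like scenes with exact ground-truth
    masks and for survival cohorts with known SIP/LIP-dependent hazards,
    so the whole pipeline can be exercised end to end without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
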