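Package: breastCompRT
Title: Breast Composition, Substructure Dosimetry and Toxicity Association
    for Breast Radiotherapy CT
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated characterisation of breast composition on planning CT
    for radiotherapy toxicity research. Provides first-order intensity
    features (median, interquartile range, uniformity) within breast
    contours, BI-RADS-like density clustering of a cohort by k-means,
    patient-specific fat/fibroglandular segmentation from a two-component
    Gaussian mixture fitted to the Hounsfield-unit histogram, substructure
    dose metrics for physical dose and EQD2 under the linear-quadratic
    model, and a proportional-odds ordinal regression workflow with
    AIC-stepwise selection linking composition and dose to ordinal toxicity
    grades. Includes a synthetic phantom and cohort generator so every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
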