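Package: lungburden
Title: Tumor Burden Quantification in Contrast-Stained Lung Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pulmonary tumor burden from ex vivo micro-CT volumes of
    iodine-in-ethanol stained mouse lungs. Implements seeded 3D region growing
    with a static gray-value tolerance criterion and an optional spherical
    radius restriction, whole-organ mask extraction, airway segmentation,
    gray-value histogram splitting, and volumetric (3D) versus single-slice
    (2D) burden estimation. Ships a synthetic stained-lung phantom generator
    with exact ground-truth labels for validating the estimators, a
    reproducible end-to-end pipeline, and a bias study comparing 2D and 3D
    burden estimates against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
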