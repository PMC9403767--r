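Package: hepaseg
Title: Segmentation of Colorectal Liver Metastases and Ablation Zones on
    Contrast-Enhanced CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end toolkit for automatic segmentation of hypo-enhancing
    liver lesions (colorectal liver metastases and thermal-ablation zones) on
    contrast-enhanced CT. Provides liver-masked preprocessing (patient-specific
    intensity normalization from the full width at half maximum of the in-liver
    histogram, voxel-size resampling), class-balanced disease-centered training
    slabs, declarative construction of standard/residual/dense 3D U-Nets and a
    hybrid 2D-3D dense W-Net with exact parameter accounting, a staged training
    protocol with cyclical learning rates and a learning-rate range finder,
    seed-and-threshold region growing on probability maps with grid-search
    tuning, lesion-level evaluation (site/patient/global Dice, median surface
    distance, detection sensitivity, false-positive decomposition), and a
    synthetic liver-phantom generator so that every stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
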