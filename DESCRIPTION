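Package: vascufem
Title: Multiscale Finite-Element Analysis of Cerebrovascular Loading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale multiscale finite-element pipeline for studying
    mechanical loading of the cerebral vasculature under controlled cortical
    impact. Generates synthetic brain-block volumes and branching vascular
    networks with calibrated diameter statistics, builds voxel-based
    hexahedral tissue meshes with embedded vessel beam elements, runs an
    explicit central-difference dynamic solver with Ogden hyperelasticity and
    Prony-series viscoelasticity, extracts refined submodels with
    displacement boundary conditions, maps peak vessel axial stress onto the
    tissue, and computes the vessel-direction versus principal-stress angle,
    correlation, partial-correlation, regression and ROC statistics that
    relate vascular anatomy to parenchymal shear stresses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
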