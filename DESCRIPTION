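Package: DILmapper
Title: Kinetic-Model Localization of Dominant Intraprostatic Lesions from
    Short Dynamic PSMA-PET and CT Perfusion
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Digital-phantom simulation and voxel-wise kinetic analysis for
    localizing the dominant intraprostatic lesion (DIL) from a 22-minute
    dynamic PSMA-PET acquisition and a 3-minute CT-perfusion scan. Implements
    the flow-modified two-tissue-compartment (F2TC) model and the adiabatic
    tissue-homogeneity (Johnson-Wilson) model with bounded multi-start
    weighted nonlinear least squares, produces the 13 voxel-wise parametric
    maps (K1, k2, k3, k4, Ki, DV, SUV Early/Late, BF, BV, MTT, PS, T0),
    screens them by paired exact Wilcoxon signed-rank tests with Bonferroni
    correction, selects a voxel-wise logistic classifier by backward
    elimination, and validates it with leave-one-patient-out cross-validation
    (error rates, ROC AUC, Dice similarity of detected lesion masks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    minpack.lm,
    lhs,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    deSolve,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
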