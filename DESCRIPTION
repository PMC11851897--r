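Package: drrpose
Title: Rigid 2D-3D X-ray/CT Registration with DRR Simulation and
    Transformer Pose Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for rigid 2D-3D registration between intraoperative
    X-ray radiographs and preoperative computed tomography volumes.
    Implements digitally reconstructed radiograph (DRR) simulation by
    Siddon ray casting under an explicit source/patient/CT coordinate
    model, pose-labelled dataset generation within clinical capture
    ranges, a dual-channel shifted-window attention encoder with
    squeeze-and-excitation reweighting and feature-pyramid fusion that
    regresses the six rigid pose parameters, intensity-based
    optimization baselines (Powell direction-set and CMA-ES with a
    gradient normalized cross-correlation objective), a Poisson-Gaussian
    noise model for robustness studies, and an evaluation suite with
    per-parameter mean absolute error, mean target registration error
    and gross failure rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
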