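Package: difcsim
Title: Monte Carlo Detection-Depth Modeling for Diffuse In Vivo Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the detectability of single fluorescent
    circulating cells in deep tissue with diffuse in vivo flow cytometry
    (DiFC). Provides a voxelized Monte Carlo photon-transport simulator for
    homogeneous turbid media with closed-form diffusion-theory oracles,
    adjoint Born-approximation fluorescence sensitivity (Jacobian) matrices
    for arbitrary source-detector separations, a peak-to-background
    detection-limit model with brightness calibration and robustness sweeps,
    a synthetic two-probe flow-phantom trace generator with ground-truth
    event logs, and the moving-median/threshold peak-detection and two-probe
    matching pipeline used to count cell detections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
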