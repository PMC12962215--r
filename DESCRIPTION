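Package: phyllotaxr
Title: Self-Compensating 3D Radial Spiral Phyllotaxis Trajectories for MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of 3D radial spiral phyllotaxis k-space trajectories
    (original single-hemisphere, pole-to-pole, and continuous variants),
    simulation of their acquisition on analytic digital phantoms under a
    parametric gradient-imperfection model (direction-odd zeroth-order phase
    offsets and per-axis gradient delays), density-compensated gridding
    reconstruction with adaptive coil combination, opposing-spoke phase and
    gradient-delay correction algorithms, and phase-cycled balanced SSFP
    T1/T2 mapping via ellipse-model inversion. Provides the diagnostic
    metrics (k-space center-phase maps, interleave jump statistics,
    artifact-energy ratios) needed to study how acquiring spokes from both
    k-space hemispheres self-compensates eddy-current phase errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
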