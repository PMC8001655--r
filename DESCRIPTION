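Package: dvctomo
Title: Digital Volume Correlation and Differential Tomography for Bone
    Microcrack Analysis
Version: 0.1.0
Authors@R:
    person("dvctomo", "developers", email = "dvctomo@example.org",
           role = c("aut", "cre"))
Description: Laboratory micro-CT post-processing toolkit for detecting and
    measuring fatigue microcracks in cortical bone. Implements projection-level
    corrections with focal-spot drift estimation from interleaved reference
    exposures, a two-step digital volume correlation (DVC) engine combining an
    integer-voxel normalized cross-correlation search with a sub-voxel 3D
    Lucas-Kanade affine refinement, a window-size calibration protocol based on
    virtual rigid-body motion experiments, local least-squares volume
    registration, differential-tomography blending of reference and loaded
    volumes, Green-Lagrange strain mapping from nodal displacement fields, and
    FWHM-based crack metrology. A synthetic bone-phantom generator with known
    ground truth (Haversian canals, speckle texture, planar microcracks,
    prescribed deformations, drifting projection series) supports validation of
    every stage without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
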