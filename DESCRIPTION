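Package: amoebokinetics
Title: Random-Walk and Cell-Shape Dynamics of Amoeboid Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of amoeboid cell migration and morphodynamics.
    Implements a generalized Langevin equation (GLE) model of the centroid random
    walk with exponential velocity memory, including exact steady-state velocity
    autocorrelation curves, positional-noise corrections, Euler-Maruyama
    simulation and parameter fitting; descriptive random-walk statistics (mean
    square displacement, speed distributions, conditional accelerations, turning
    angles); cell-boundary analysis of binary mask movies (equal-arc contour
    resampling, curvature and normal-velocity kymographs, traveling curvature-wave
    tracking, leading-edge lifetimes and a closed-form persistence-time
    estimator); elliptic Fourier shape descriptors with power-spectrum principal
    component analysis and deformation-velocity mode coupling; and seeded
    synthetic-data generators (GLE trajectory ensembles, 1D persistent-random-walk
    angle series, rasterized deforming-cell mask movies) that exercise every
    analysis stage with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
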