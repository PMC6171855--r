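Package: carilow
Title: Face Caricaturing and Low-Vision Simulation for Identity-Perception Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based shape-only face caricaturing at a defined strength
    (piecewise-affine warping away from a category-matched average face),
    simulation of two low-vision viewing formats (eccentricity-dependent
    Gaussian blur and phosphenised prosthetic vision with electrode dropout),
    a parametric synthetic-face generator with ground-truth landmarks in a
    147-point hand-annotation scheme and the widely used 68-point automatic
    scheme, pairwise dissimilarity-rating experiment schedules, a simulated
    rater with a controllable true caricature-effect structure, and the
    repeated-measures analysis of the resulting ratings including the
    relative-effectiveness statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    mgcv,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    readxl,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
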