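Package: stereomire
Title: Simulated Stereo Microscope Surface Reconstruction with Adaptive
    Projected Dot Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained virtual testbed for microscopic stereo surface
    reconstruction under projected near-infrared-style dot patterns. Provides
    a synthetic ear-like phantom with multimodal fiducial markers, a pinhole
    stereo-microscope and pattern-projector simulator with z-buffer rendering,
    Zhang-style stereo calibration with rectification and a per-zoom lookup
    table, semi-global block matching and triangulation to metric point
    clouds, Horn absolute-orientation registration with closest-point RMSE
    scoring inside a region of interest, and a Gaussian-process Bayesian
    optimizer with expected-improvement acquisition that tunes pattern dot
    size and spacing per zoom level. An experiment driver reproduces a
    4-illumination-method by 5-zoom-level by 10-repeat comparison grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
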