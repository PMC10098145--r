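Package: stencode
Title: Spatiotemporal Acoustic Encoding and Compressive Photoacoustic Image Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico toolbox for single-shot photoacoustic imaging through a
    passive spatiotemporal acoustic encoder (an ultrasonic pipe mounted on a
    right-angle prism read out by a single-element transducer). Provides a
    staggered-grid finite-difference time-domain solver for linear acoustics in
    heterogeneous media with perfectly matched layers, builders for the encoder
    geometry with optional randomized rough prism edges and configurable
    top-boundary layers, pointwise and reciprocity-based calibration of the
    per-pixel impulse-response system matrix, boundary-independent time
    windowing, and compressive image reconstruction by a two-step iterative
    shrinkage/thresholding (TwIST) solver with total-variation regularization.
    Includes synthetic phantoms, matrix-mode synthetic operators, image-quality
    metrics, and orchestrated experiments contrasting windowed reconstruction
    against full-trace (ergodic-relay style) reconstruction under changed
    boundary conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    generics,
    ggplot2,
    yaml,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
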