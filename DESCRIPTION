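Package: drowsecam
Title: Drowsiness Recognition from Face and Eye Images with Attention and
    Feature-Geometry Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for frame-level drowsiness recognition from facial
    images. Builds the three canonical network inputs (face thumbnail,
    stacked eye pair, and their horizontal fusion) from eye landmarks,
    trains a small batch-normalized convolutional network with an exact
    per-layer parameter accounting, explains its decisions with
    gradient-weighted class activation mapping (Grad-CAM), and
    quantifies feature-space quality with principal-component
    visualization and a tie-aware leave-one-out k-nearest-neighbour
    accuracy curve (KNN-Sigma). Ships a parametric synthetic face/eye
    generator with known class and gender structure so the whole
    pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
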