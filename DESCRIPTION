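Package: fluoropose
Title: Instrument Pose Estimation from Single Fluoroscopic Images via
    Pseudo-Landmark Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the five-parameter pose (in-plane position, forward
    angle, out-of-plane projection angle and source-object depth) of a small
    radio-opaque surgical fiducial from a single X-ray-like image. The
    pipeline is modular: a region of interest around a prior pose guess is
    normalized into a standard-pose patch, a convolutional network regresses
    six geometrically defined pseudo-landmarks arranged in a metric cross,
    and the pose is recovered in closed form by inverting the pinhole
    projection of the landmark cross (line fits, intersection, and
    magnification/foreshortening relations). A parametric radiograph
    simulator (ray-traced fiducial meshes over anatomy-like random-field
    backgrounds, Beer-Lambert compositing) provides exact-ground-truth
    training and evaluation data, making the whole pipeline trainable and
    testable without external datasets. The convolutional regressor and its
    Adam/MSE training loop are implemented in single-precision C++ for
    CPU-scale training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
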