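Package: gazecomp
Title: Eye-Camera Location Compensation and Eye-Feature Undistortion for
    Interpolation-Based Gaze Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and improving interpolation-based video
    eye-tracking methods. Includes a geometric eye-tracker simulator (rotating
    schematic eye with corneal refraction and glints imaged by a pinhole
    eye-camera), second-order polynomial and homography gaze mappings,
    eye-camera location compensation by polynomial normalization of the eye
    feature distribution into a unit square, eye-feature undistortion with a
    radial/tangential/thin-prism lens-distortion model fitted by nonlinear
    least squares, epipolar diagnostics (fundamental matrix and epipole of the
    virtual eye-camera), and Gaussian high-accuracy analysis of gaze errors,
    together with readers and writers for annotated eye-tracking CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    vegan
Config/testthat/edition: 3
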