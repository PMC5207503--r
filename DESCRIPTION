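Package: vbsar
Title: Virtual Depth-Camera Framework for Single-View Body Surface Area
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A virtual laboratory for studying how much of the whole body
    surface area (WBSA) a single depth-camera view can recover. Generates
    synthetic parametric humanoid meshes and virtual populations, simulates a
    2.5D depth sensor by per-pixel ray casting under a pinhole camera model at
    configurable azimuth, elevation and distance, extracts the view body
    surface area (VBSA) as ground truth from visible-triangle identifiers,
    corrupts acquisitions with axial/lateral sensor noise and depth-map holes,
    reconstructs surfaces from organized single-view point clouds, and fits
    and cross-validates per-angle linear models predicting WBSA from VBSA and
    optional anthropometric measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lmtest,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
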