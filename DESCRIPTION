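Package: pactfbp
Title: Learned Half-Scan Filtered Backprojection for 3D Photoacoustic
    Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for three-dimensional photoacoustic computed tomography
    (PACT) with hemispherical ("half-scan") measurement apertures formed by
    a rotated arc probe.  Provides a matched discrete forward/adjoint
    spherical-mean operator pair, a standard universal-backprojection
    baseline, a strictly linear multi-resolution data-filtering network
    with physics-informed per-axis padding (cyclic views, zero time,
    learned ring padding), and the supervised training procedure that
    learns the half-scan data filter so that filtered backprojection
    reconstructs accurate volumes from limited-view data.  Includes seeded
    synthetic phantom generators, measurement-domain preprocessing (noise
    injection, Gaussian low-pass apodization, adaptation of mismatched
    acquisitions), and MSE/SSIM/line-profile evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
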