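Package: orthoreg
Title: Orthogonal-View 2-D/3-D Rigid Registration Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for intensity-based rigid registration of head CT to
    biplanar radiographs via an intermediate 3-D reconstruction: perspective
    digitally-reconstructed-radiograph (DRR) rendering with a pinhole C-arm
    model, CT preprocessing (max-ellipse detection, elliptical-cylinder crop,
    bone thresholding), MSE-driven 3-D/3-D rigid registration by gradient
    descent with analytic gradients and a multi-resolution pyramid, synthetic
    head-phantom benchmark generation with a pseudo-reconstruction simulator,
    and evaluation by mean target registration error (mTRE) and gross failure
    rate (GFR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    png,
    withr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
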