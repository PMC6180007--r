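Package: psvrgrappa
Title: GRAPPA Parallel-MRI Reconstruction with Complex Proximal Support
    Vector Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for Cartesian parallel-MRI k-space reconstruction.
    Implements the GRAPPA interpolation scheme, in which each missing
    k-space sample is synthesized from a window of acquired neighbours
    across all coils, with interpolation weights fitted on auto-calibration
    (ACS) lines either by ordinary least squares or by a complex-valued
    proximal support vector regression (PSVR) with kernel mapping (linear,
    polynomial, radial-basis and wavelet kernels).  Includes a synthetic
    multi-coil phantom generator with known ground truth, sum-of-squares
    coil combination, NMSE/PSNR quality metrics, and an experiment harness
    for interpolation-window sweeps and kernel comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
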