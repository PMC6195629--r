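Package: SCTdetect
Title: Detection and Kinetic Analysis of Spontaneous Calcium Transients in
    Fluorescence Time-Lapse Movies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated detection of fast, low-amplitude spontaneous calcium
    transients (SCTs) in noisy 16-bit fluorescence time-lapse movies. The
    pipeline applies a separable 3D Gaussian filter, a moving-baseline
    dF/F0 transform, a robust per-frame threshold (median plus a multiple of
    the interquartile range), 3D connected-component grouping of
    supra-threshold voxels into dynamic ROIs, and size/mask filters. Event
    kinetics (10-90% rise time, 90-10% decay time, FWHM, amplitude, area,
    integrated amplitude) are measured with sub-frame linear interpolation.
    A synthetic-movie generator with ground truth, an SNR sweep, and a
    sigmoid fit of the true-positive-rate curve quantify detection
    performance as a function of signal-to-noise ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    igraph,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
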