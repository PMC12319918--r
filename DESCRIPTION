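Package: fuscouple
Title: Coupling Analysis for Simultaneous Functional Ultrasound and
    Neuropixels Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify neurovascular coupling between Power-Doppler
    functional ultrasound (fUS) image series and simultaneously recorded
    Neuropixels spike trains. Implements baseline-relative response
    normalization (percent change in Doppler intensity and spike rate),
    Monte-Carlo probe-trajectory alignment by correlation maximization,
    trajectory-based region averaging, temporal transfer-function estimation
    by lag-stacked ridge regression with gamma-kernel parameterization, the
    spatiotemporal forward model (spatial Gaussian times temporal gamma
    convolution), amplitude calibration slopes between modalities, and
    spatial-spread statistics. A fully specified synthetic-session generator
    co-simulates Poisson spiking and hemodynamics with known ground truth so
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
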