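Package: gpecg
Title: Data-Driven Gaussian Process Filtering for ECG Denoising
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoises electrocardiograms with a data-driven Gaussian process
    filter built on the ECG phase domain: beats are segmented at the midpoints
    between successive R peaks, warped onto a fixed number of phase samples
    with aligned R peaks by sparse binary transformation matrices, and the
    phase-domain sample mean and covariance supply the Gaussian process prior.
    The posterior mean then combines each measured beat with the learned beat
    template, weighted per sample by signal versus noise variance. Includes
    baseline-wander removal, a modified Pan-Tompkins R-peak detector, a
    Symlet-5 SURE soft-threshold wavelet denoiser as benchmark, a synthetic
    ECG generator with analytically known landmarks, and an evaluation harness
    for signal-to-noise-ratio improvement and QT-interval estimation error.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
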