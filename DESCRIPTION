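Package: pwnet
Title: Simultaneous B-Mode Imaging and Cyst Segmentation from Single
    Plane-Wave Ultrasound Channel Data
Version: 0.1.0
Authors@R:
    person("pwnet", "developers", email = "pwnet@example.org",
           role = c("aut", "cre"))
Description: Tools for single plane-wave ultrasound imaging of anechoic
    cyst-like targets. Provides a point-scatterer phantom simulator for
    linear-array plane-wave acquisitions, IQ demodulation and
    delay-and-sum (DAS) beamforming with subaperture variants, a
    single-encoder/dual-decoder fully convolutional network that maps
    raw IQ channel data to a paired B-mode-like image and cyst
    segmentation, classical baselines (binary thresholding with
    morphological filtering, non-local means), and an evaluation suite
    (Dice similarity coefficient, contrast, tissue SNR, generalized
    contrast-to-noise ratio, PSNR, coefficient of variation) with
    automated region-of-interest conventions and exclusion logic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
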