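Package: pearspad
Title: Chlorophyll (SPAD) Estimation from Leaf Reflectance Spectra by
    Wavelet and Derivative Preprocessing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates relative chlorophyll content (SPAD) of orchard
    leaves from field reflectance spectra (350-2500 nm). Implements the
    full chemometric chain: median-filter smoothing, classical spectral
    transforms (1/R, log10 R and their first derivatives), multi-level
    orthonormal Haar discrete wavelet decomposition with a
    coefficient-to-wavelength mapping, Pearson-correlation band screening
    with separation-constrained greedy selection, and two-band ordinary
    least squares or NIPALS partial least squares calibration with
    R-squared/RMSE validation on a held-out split. Includes a synthetic
    spectra generator that plants chlorophyll absorption wells, a red
    edge, smooth baseline drift and high-frequency dust noise, so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
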