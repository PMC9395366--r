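Package: tddos
Title: Time-Domain Diffuse Optical Spectroscopy of Turbid Slabs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating absorption and reduced scattering spectra of
    soft tissue from time-domain diffuse optical spectroscopy (TD-DOS)
    transmittance measurements. Provides a white Monte Carlo forward model
    (null-absorption photon transport through a slab with analytical
    Beer-Lambert absorption scaling), an analytical diffusion-approximation
    solution with extrapolated boundaries, instrument-response-function
    convolution and Levenberg-Marquardt inversion of photon time-of-flight
    histograms, Mie power-law scattering fits, effective transport coefficient
    and fluence-rate dosimetry, study-level variability statistics, and a
    synthetic-data generator emulating an ex vivo pancreas measurement
    campaign (600-1100 nm, fresh versus frozen-thawed tissue).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
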