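Package: xfiquant
Title: Simulation and Quantitative Reconstruction for X-Ray Fluorescence
    Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for scanning-beam X-ray fluorescence imaging (XFI) of
    mouse-sized objects with monochromatic pencil beams. Provides a Monte
    Carlo photon transport engine with Klein-Nishina Compton sampling and
    forced-detection variance reduction to model the multiple-Compton
    spectral background, a silicon drift detector response model, Gaussian
    peak fitting with significance estimation (Z = S/sqrt(B)), beam-bandwidth
    sensitivity design studies, reference-foil flux calibration,
    attenuation-corrected per-pixel marker mass reconstruction for
    multi-element (iodine/palladium) cell-tracking maps, and local energy
    dose estimation against a configurable dose limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
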