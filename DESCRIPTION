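Package: gdei
Title: Gaussian Rocking-Curve Retrieval for Analyzer-Based X-Ray Imaging
Version: 0.1.0
Authors@R:
    person("SYRMEP", "Tools", email = "gdei@example.org", role = c("aut", "cre"))
Description: Analytical separation of apparent absorption, refraction angle
    and ultra-small-angle scattering width from three analyzer-based X-ray
    phase-contrast images, under a Gaussian model of the analyzer rocking
    curve. Includes the closed-form forward model and its exact three-image
    and two-image inversions, Gaussian rocking-curve fitting and working
    point location, a Monte Carlo simulator of analyzer-based images of
    rod-and-foil phantoms, a multiple-image-radiography (MIR) reference
    retrieval, baseline TIFF input/output with flat/dark correction, and a
    command-line interface tying simulation, retrieval and validation
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
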