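Package: qdri
Title: Quantitative Diffuse Reflectance Imaging of Tissue Margins
Version: 0.1.0
Authors@R:
    person("QDRI", "Maintainer", email = "qdri@example.org", role = c("aut", "cre"))
Description: Tools for quantitative diffuse reflectance imaging (QDRI) of
    turbid media with a multiplexed fiber-optic probe: forward Monte Carlo
    photon transport for an 8-around-1 fiber channel in homogeneous and
    layered media, a fast single-baseline ("scalable") reflectance model
    and lookup tables, Mie-sphere and chromophore optics, reference-phantom
    calibration and nonlinear least-squares inversion of reflectance
    spectra to absorption and reduced scattering, raster-scan stitching of
    49-channel frames into sub-millimetre parameter maps, and empirical-CDF
    / Kolmogorov-Smirnov landscape statistics of beta-carotene to
    scattering ratio maps. A synthetic-data module emulates phantom
    dilution series and breast-margin specimens so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
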