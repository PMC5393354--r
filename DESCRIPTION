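Package: epiddose
Title: Portal Dosimetry with Amorphous-Silicon EPID Cine Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts cine-mode images from an amorphous-silicon flat-panel
    electronic portal imaging device (EPID) into absolute two-dimensional
    water-equivalent dose maps. The chain covers dark-field/flood-field
    pixel corrections, beam-profile restoration, regularised deconvolution
    of the detector glare kernel to incident photon fluence, pencil-beam
    kernel convolution to dose in water at the depth of dose maximum, and
    absolute calibration against a reference delivery. Includes gamma-index
    comparison of dose distributions, a desk-scale photon Monte Carlo for
    generating pencil-beam kernels under the kerma approximation, and a
    synthetic acquisition simulator (panel gain/dark structure, Poisson
    noise, flattened and flattening-filter-free beam profiles) so the whole
    inverse pipeline is testable end to end without linac data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
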