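Package: stedclust
Title: Two-Channel STED Cluster Analysis for Membrane Nanodomains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies nanoscale protein clusters in two-channel
    super-resolution (STED) micrographs of membrane sheets. Detects local
    intensity maxima with a noise-tolerance (prominence) criterion,
    classifies maxima as clusters by Gaussian linescan fits, measures
    object-based two-channel colocalization by nearest-neighbor distance,
    computes neighbored-maxima crowding statistics with one- and
    two-Gaussian mixture decomposition, and runs through-origin
    inter-channel intensity regression with a noise gate. Includes a
    synthetic membrane-sheet image generator (clustered point process,
    Gaussian PSF, Poisson and read noise) that provides ground truth for
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
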