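Package: fibrilstats
Title: Morphometrics and Spatial Statistics of Amyloid Fibrils in
    Segmented Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative in-situ analysis of neuronal amyloid
    inclusions from segmented cryo-electron tomograms: fibril length and
    cytosolic density, persistence length from tangent-correlation decay
    with derived Young's modulus, nearest-distance fields between fibrils
    and organelle membranes and between membranes of different organelles,
    and a Monte-Carlo rigid-motion null model with Kolmogorov-Smirnov
    comparison of close-contact frequencies. Includes a synthetic scene
    generator (worm-like-chain fibrils, voxelized organelles in a thin
    lamella) so every stage is testable without tomographic data, readers
    and writers for MRC2014 label volumes and CSV/VTK polylines, and a
    command-line pipeline.
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
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
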