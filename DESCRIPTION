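Package: cortexquant
Title: Quantification of Cortical Membrane Ingression and Sub-Cortical
    Microtubule Foci in Oocyte Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Maintainer", "cortexquant", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of multi-channel time-lapse
    z-stacks of C. elegans oocytes during meiosis I polar body extrusion.
    Implements convex-hull-based measurement of cortical membrane
    ingressions from a single focal plane, detection and three-class
    intensity classification of sub-cortical microtubule foci (sCMFs) in
    3-D, threshold-based patch and microtubule intensity quantification
    with 0-100 normalization and percent depletion, relative standard
    deviation texture metrics, drift correction, normalized anaphase-B
    time binning, and a synthetic movie generator with planted ground
    truth for end-to-end validation.  Includes Yen and Triangle automatic
    histogram thresholding, rank and Gaussian filters, and minimal
    uncompressed multi-page TIFF input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
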