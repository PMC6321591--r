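Package: pmfpath
Title: Umbrella Sampling, WHAM and Minimum-Energy-Path Analysis on
    Reaction-Coordinate Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Free-energy and reaction-pathway analysis along chemical
    reaction coordinates: umbrella-sampling simulation of biased
    reaction-coordinate time series on analytic model landscapes,
    weighted-histogram (WHAM) reconstruction of one- and two-dimensional
    potentials of mean force with three-block error estimates,
    minimum-(free-)energy-path extraction on gridded energy surfaces by a
    weighted-graph shortest path, chain-of-states path refinement with
    saddle-point location, reaction coordinates defined as signed linear
    combinations of interatomic distances, and transition-state-theory
    conversion between first-order rate constants and activation free
    energies.  Bundled model surfaces emulate the two-basin dissociative
    phosphoryl-transfer landscapes of phosphoserine phosphatase.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
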