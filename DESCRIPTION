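Package: taxmature
Title: Taxonomic Maturation Analysis of Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct phylogenetic knowledge at historical time
    slices of taxonomic study and to quantify how newly described species
    reshape a dated phylogeny. Given a rooted ultrametric chronogram and the
    year of scientific description for each species, the package prunes the
    tree to every point in taxonomic history and tracks the branch lengths
    added by new species, the gamma statistic of tree shape together with a
    random-pruning null distribution (observed minus expected gamma and its
    recent slope), and the phylogenetic diversity contributed per time
    interval. It can forecast present-day gamma from a past knowledge state
    by random tip addition, follow trait-evolution inferences (independent
    contrast rates, Pagel's lambda) across taxonomic history, and simulate
    complete synthetic inputs: birth-death chronograms, description-year
    histories with controllable phylogenetic bias, and lambda-transformed
    Brownian traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    MASS,
    graphics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
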