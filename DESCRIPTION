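Package: brushfoot
Title: Phylogenetic Analysis of Forelimb Reduction in Butterflies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolutionary reduction of the first
    thoracic (T1) limb in butterflies on a fixed phylogeny. Reconstructs
    continuous limb-segment lengths (femur, tibia, combined tarsus, whole
    limb) at ancestral nodes by unweighted squared-change parsimony,
    computes the relative T1 length r = T1 / mean(T2, T3) at every node,
    classifies nodes against a reduction threshold (default 80%), and
    detects the branches on which limb reduction evolved. Includes the
    13-taxon study topology as a fixture, converts digitized landmark
    chains into segment lengths, simulates Brownian-motion trait tables
    with planted clade-specific reductions for end-to-end testing, and
    draws the pairwise limb-length allometry panels with isometry and
    threshold reference lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
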