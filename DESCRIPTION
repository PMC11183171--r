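Package: rhizonet
Title: Cross-Kingdom Root Microbiota Networks, Community Assembly, and
    Slope Multifunctionality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative workflow linking root-associated microbiota
    (heterotrophic bacteria, rhizobia, and arbuscular mycorrhizal fungi)
    to ecosystem multifunctionality along an eroded hillslope.  Provides
    ecosystem multifunctionality indices (z-score averaging and principal
    axes), compositionally robust signed co-occurrence network inference
    (centered log-ratio transform, L1-penalized neighborhood selection,
    StARS stability selection), network topology and node-role analysis
    (Zi-Pi module roles, Kleinberg hub-centrality keystones, per-sample
    subnetworks, community-level positive/negative biotic-association
    scores), null-model quantification of community assembly processes
    (abundance-weighted betaMNTD, betaNTI, Bray-Curtis Raup-Crick, and the
    five-process classification), permutation multivariate statistics
    (Mantel, PERMANOVA, constrained PCoA, variation partitioning), and a
    synthetic-data generator with planted ground truth emulating a
    three-position by six-replicate slope design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    biomformat,
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
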