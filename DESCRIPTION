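Package: matdiversity
Title: Phylogenetic and Trait Diversity of Layered Microbial Mat Communities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of millimeter-scale biodiversity in layered microbial
    communities such as intertidal mats. Implements similarity-sensitive
    (phylogenetic) Hill-number diversity profiles built on a historical-species
    branch decomposition, rarefied mean-pairwise-distance (MPD) dispersion
    statistics against independent-swap, taxa-label and phylogeny-pool
    permutation null models with configurable taxa-pool scopes and guild-level
    tests, unweighted UniFrac beta diversity, and resampling null models for
    ortholog-group (KO/COG/NOG) trait richness. A synthetic-data generator
    produces trees, phylogenetically structured communities, count tables and
    trait tables so that every stage is testable without external sequence
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Rcpp,
    jsonlite,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
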