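Package: NetFEA
Title: Network-Based Functional Enrichment Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assesses whether the genes annotated with a biological
    function are more connected within an interaction network than
    expected at random, generalizing the one-sided Fisher's exact test
    to networks. The connectivity of the subgraph induced by a
    function's genes is summarized by its non-increasing sequence of
    connected-component sizes and tested against two permutation
    nulls, uniform resampling of gene sets from the universe and
    degree-preserving edge rewiring of the universal network. Also
    scores how the addition of an interaction set improves a
    function's network coherence via the log-ratio of enrichment
    p-values with and without those edges. Includes readers for
    edge-list and SIF networks, GMT and tabular annotations, OBO
    ontologies with true-path-rule propagation, and deterministic
    synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: NetworkEnrichment, GraphAndNetwork, GeneSetEnrichment,
    GO, Network
RoxygenNote: 7.3.3
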