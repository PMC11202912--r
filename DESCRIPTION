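Package: linkSAC
Title: Link Prediction with Average-Centrality-Filtered Common Neighbors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Similarity indices for link prediction in undirected, unweighted
    interaction networks. Implements the SAC family (common-neighbor counts
    filtered by an above-graph-average centrality test, instantiated with
    degree, betweenness, closeness and clustering-coefficient centralities),
    the five classical local indices (common neighbors, Jaccard,
    Adamic-Adar, resource allocation, preferential attachment) and two
    centrality-based indices (CCPA, KNLP), together with an edge-holdout
    evaluation protocol reporting AUROC and AUPR overall and on top-k
    candidate subsets. Ships a reconstructed eight-node worked-example
    fixture with its derivation oracle, seeded random-graph generators, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
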