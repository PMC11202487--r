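Package: cdpath
Title: Centrality Degree Paths and Spreading-Based Ranking of Influential Nodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Ranks influential nodes in undirected simple networks with the
    centrality-degree-paths (CDP) score: the squared node degree divided by the
    number of simple paths of bounded length starting at the node. Ships the
    classic comparison centralities (degree, closeness, betweenness, PageRank
    and an attribute-weighted degree variant), a discrete-time stochastic SIR
    spreading simulator that measures per-node spreading efficiency, and
    rank-agreement statistics (Pearson, Spearman, Kendall tau, top-k overlap)
    for validating rankings against spreading ground truth. Reads edge-list,
    GML and Pajek graph files and includes generators for standard test
    topologies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
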