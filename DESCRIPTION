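Package: subpathnet
Title: Disease-Metabolic Subpathway Network Construction and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mines k-clique subpathways from KEGG-style metabolic pathway
    graphs, links diseases to subpathways by hypergeometric gene-set
    enrichment, and assembles the resulting bipartite disease-subpathway
    network. Provides network-biology statistics for such networks:
    degree-distribution null ensembles, bipartite dyadicity and
    heterophilicity (BD/BH) class-clustering measures, disease diversity,
    gene-class ratio trends along node degree, and within-subpathway
    coexpression contrasts. Ships seeded synthetic-data generators that
    emulate every input (pathways, disease gene sets, gene class labels,
    tissue expression) with known ground truth, so the full pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
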