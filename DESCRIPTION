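Package: coremod
Title: Core Disease Module Identification in Weighted Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies small, structurally well-defined "core" disease
    modules in weighted biological networks. Provides community quality
    measures (modularity, conductance, CEIL, per-node core scores),
    baseline partitioners (resolution-parameterized Louvain, Markov
    clustering, CEIL-objective local moving), four core-module extraction
    frameworks (clustering ensembles via pairwise Jaccard consensus,
    perturbation consensus, iterative reclustering of oversized modules,
    minimum-outgoing-edge cores), personalized-PageRank seed expansion
    with disease-gene, HITS and spread-hub seed selection, resolution of
    overlapping covers into partitions, Fisher-method GWAS enrichment
    scoring at a configurable FDR, trait comorbidity networks, and a
    planted-partition benchmark generator with synthetic gene-score
    tables so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
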