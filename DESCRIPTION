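Package: rnanet
Title: Network Analysis of RNA-Seq Time Series Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream network analysis for RNA-Seq count data: CPM/log-CPM
    scaling, low-expression filtering and trimmed-mean-of-M-values (TMM)
    normalization factors; weighted gene co-expression network construction
    (correlation similarity, soft-threshold selection against scale-free
    topology, topological overlap, average-linkage module detection, module
    eigengenes and module merging); gene ontology enrichment of gene scores by
    Kolmogorov-Smirnov testing over a propagated ontology; graph analytics on
    differentially-expressed-gene networks (edge reduction, DEG overlap,
    centralities, hub extraction, visual attribute encoding); and bipartite
    transcription-factor-to-gene regulatory networks built from robust
    biweight midcorrelation and from regulator path tables. Includes a
    deterministic synthetic-data generator for the full set of pipeline
    inputs and a command-line orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
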