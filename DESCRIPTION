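Package: colonykit
Title: Downstream Analyses for Colonial Cnidarian Cell Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for the downstream analysis of single-cell
    atlases of colonial animals sampled by body part. Implements colony-part
    compositional enrichment (log2 odds ratios with pseudocounts, exact
    Fisher tests, tiered Benjamini-Hochberg FDR), ensemble co-occurrence
    cell-type trees, weighted co-expression networks (soft-threshold
    adjacency, topological overlap, module detection and module graph
    statistics including transcription-factor closeness centrality),
    transcription-factor evidence pooling and class statistics, a
    glycine-repeat (XGnX) protein-architecture scanner with signal-peptide
    region overlay, and cross-species marker gene-set score transfer via
    one-to-one orthologs. Ships seeded generators for synthetic count
    matrices, correlated gene modules and repeat-bearing proteins so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ape,
    Biostrings,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
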