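Package: otunet
Title: Depth-Stratified Soil Microbiome Analysis and Co-Occurrence Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for amplicon OTU-table analysis of
    depth-stratified, long-term fertilization soil experiments. Covers
    singleton removal, rarefaction and Good's coverage, Hellinger-transformed
    Bray-Curtis community statistics (PCoA, ANOSIM, distance-based redundancy
    analysis with permutation tests), negative-binomial Wald differential
    abundance with enriched/depleted OTU classification, and Spearman
    co-occurrence network inference with random-matrix-theory threshold
    selection, greedy-modularity module detection, betweenness-based keystone
    identification, and module-environment Mantel tests. Ships a synthetic
    community generator with machine-readable ground truth for validating
    every stage, and a subcommand command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
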