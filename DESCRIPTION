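Package: fusionrank
Title: Transfer-Learning Network Fusion for Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns a fused gene-gene similarity network for a target cancer
    cohort that has expression data but no known pathogenic genes, by
    transferring knowledge from a source cohort with both expression and
    pathogenic-gene labels. A cross-domain affinity matrix (absolute Pearson
    correlation), a large-margin nearest-neighbor embedding of the labeled
    source genes, and a graph-Laplacian regularized alternating optimizer
    jointly produce the fused network; target genes are then prioritized by
    network propagation (PRINCE-style random walk with restart, or
    personalized PageRank). Includes a seeded synthetic-data generator with
    planted co-expression modules and pathogenic genes so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
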