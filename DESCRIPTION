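Package: stnet
Title: Spatiotemporal Co-Expression Protein Interaction Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds dynamic spatiotemporal protein-protein interaction networks for a
    query gene set (for example, a copy-number-variant locus) by integrating a
    developmental expression matrix with a physical interactome. Samples are
    partitioned into developmental-period by brain-region intervals; within each
    interval, physical interactions are retained when the two genes are co-expressed
    (Spearman correlation above a threshold). Per-interval co-expressed-pair fractions
    for the query set are tested against three control pair universes with Fisher's
    exact test and Benjamini-Hochberg correction. Significant networks are compared by
    node overlap and partner-ratio ANOVA, driver genes are ranked by radiality
    centrality, and network proteins are tested for gene-set over-representation with
    the cumulative hypergeometric distribution. A synthetic-data generator with planted
    co-expression modules supports end-to-end calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
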