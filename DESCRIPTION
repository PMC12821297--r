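Package: xsigmeta
Title: Cross-Study Meta-Analysis of Differential-Expression Signatures
Version: 0.1.0
Authors@R: person("Signature", "Meta-Analysis Team", role = c("aut", "cre"),
    email = "xsigmeta@users.noreply.github.com")
Description: Tools for meta-analysing gene-level differential-expression
    summary tables across many studies: rank-based normalization of log2
    fold changes to [-1, 1], Spearman-correlation hierarchical clustering
    of dataset signatures with branch-height and positive-dominance
    cluster calling, robust rank aggregation of gene lists from its beta
    order-statistic definition, directional recurrence scoring,
    Fisher-exact over-representation against GMT gene-set libraries,
    permutation-calibrated marker (GWAS) set enrichment with
    quantile-threshold statistics, and weighted key-driver analysis on
    gene networks. Includes a synthetic-data generator that plants
    cluster structure, consistent genes, enriched sets, network hubs and
    marker associations so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
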