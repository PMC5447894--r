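Package: trichoseq
Title: Gene Activity Calling and Differential Expression for Single-Cell-Type
    RNA-Seq Contrasts
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for contrasting a single-cell-type RNA-seq
    transcriptome (such as root hairs scraped from primary roots) against a
    multi-cell-type reference tissue. Classifies each gene as
    transcriptionally active or inactive per sample type with a hierarchical
    negative-binomial model fitted by empirical Bayes, using TMM and
    length/GC-content offsets for normalization; performs precision-weighted
    differential expression with moderated t-statistics and
    Benjamini-Hochberg FDR control; runs singular enrichment analysis of
    gene lists against an expressed-gene background; and provides QC views
    (multidimensional scaling, hierarchical clustering, row-relative
    expression heatmaps) and qPCR standard-curve utilities. Ships a seeded
    negative-binomial count simulator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    jsonlite
Config/testthat/edition: 3
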