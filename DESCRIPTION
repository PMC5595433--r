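Package: orthostage
Title: Cross-Species Transcriptome Stage Mapping and Convergent Co-Option
    Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative transcriptomics toolkit for mapping a query
    species' developing organ onto a reference species' developmental
    series and for screening for convergent gene co-option between organs.
    Provides presence/absence expression calling by the 1%-of-mean rule,
    simplified negative-binomial differential expression (median-of-ratios
    size factors, method-of-moments dispersion, Wald tests,
    Benjamini-Hochberg adjustment), rank-based Spearman stage-similarity
    matrices with control-organ contrasts, stage-partition chi-square
    enrichment, four-way presence/absence ortholog set-logic screens with
    control tissues and hypergeometric over-representation analysis, plus
    a negative-binomial synthetic-data generator with planted ground truth
    and a config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
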