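Package: regenatlas
Title: Binary Expression Pattern Atlases and Baseline-Subtracted
    Gene-Set Enrichment for Time-Course RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building stage-resolved expression atlases from
    time-course bulk RNA-seq count data. Counts are filtered and
    normalised by median-of-ratios size factors, all pairs of timepoint
    groups are compared with a moderated negative-binomial Wald test,
    and each gene's significant up/down relations are condensed into a
    per-gene hierarchy that is scored against every binary
    high/low-per-timepoint pattern; the best-scoring pattern per gene
    forms a binary gene-by-timepoint matrix. Curated, homology-mapped
    gene sets are then profiled along the timeline as active
    percentages with a hypergeometric null baseline and confidence
    band subtracted (floored at zero), and tested for
    over-representation with an exact hypergeometric test and
    Benjamini-Hochberg correction. A negative-binomial simulator with
    planted binary patterns and planted gene sets supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
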