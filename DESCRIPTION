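Package: neuroscore
Title: Additive Multi-Omic Gene Scoring for Central Nervous System
    Disease-Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an additive five-metric evidence score (0-5 points)
    that prioritizes candidate central-nervous-system disease genes from
    gene-level constraint, regional coding constraint, brain expression,
    de novo variant burden, and exon-index metrics, together with the
    statistical machinery used to build and validate such a model:
    per-metric chi-squared screening, multiple logistic regression with
    backward elimination, per-score-level odds ratios, case-control
    copy-number-variant (CNV) burden comparison, mouse-ortholog phenotype
    enrichment, recurrent-CNV region profiling, and synthetic-data
    generators with controllable effect sizes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
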