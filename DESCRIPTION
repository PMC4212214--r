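Package: ARShift
Title: Rank Product Differential Expression and Stem-to-Root Identity
    Tracking for Adventitious Rooting Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of time-course expression data recorded in the stem
    base of cuttings during adventitious root formation. Implements the
    two-class Rank Product statistic with permutation-based significance
    and percentage-of-false-positives estimates, M-value (log2 ratio)
    filtering with a joint significance rule, subtraction of wound-response
    genes identified from a wounded-vs-fresh leaf contrast, tracking of
    stem-base- and root-identity gene sets against an absolute intensity
    cutoff, and functional-category over/under-representation by a fold
    criterion. Includes a synthetic time-course generator with planted
    differential expression, wound-shared genes, organ-identity
    trajectories and category enrichment, so that every pipeline stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
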