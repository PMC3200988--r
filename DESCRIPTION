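Package: minregnet
Title: Minimal Transcription-Factor Regulatory Networks from Two-Class
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs minimal transcription-factor (TF) regulatory
    networks from two-class microarray expression data. Implements
    permutation-based Significance Analysis of Microarrays (SAM) with a
    zero-FDR delta rule and a two-fold-change filter, an iterative
    training/test resampling framework for stable differential-expression
    calls, position-weight-matrix promoter scanning with binomial
    over-representation p-values for TF-target prediction, assembly and
    pruning of minimal regulatory networks (every target regulated by at
    least two TFs) with hypergeometric pathway enrichment, and set-algebra
    comparison of networks across tumour types. A synthetic-data generator
    plants known differentially expressed genes and regulatory edges so
    that every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
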