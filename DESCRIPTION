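Package: HomoeoExpress
Title: Homoeolog Expression Analysis for Synthetic Allopolyploids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of homoeolog-level gene expression in newly synthesized
    allopolyploids relative to their diploid parents. Provides a negative
    binomial differential-expression engine (median-of-ratios size factors,
    moment-based dispersion estimation with trend shrinkage, Wald tests with
    Benjamini-Hochberg correction), exclusion filters for homoeologous
    exchange (HE) regions, unplaced scaffolds, extreme mean counts and
    transcript-length disparity, the nine-mode classification of homoeologous
    pair expression (conserved, convergent, divergent, reversed regulation),
    per-subgenome DEG summaries with chromosomal distribution tracks,
    one-tailed hypergeometric GO over-representation, and a negative binomial
    count simulator that plants known expression modes and HE copy-number
    effects so every stage of the pipeline can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
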