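Package: gprimescan
Title: QTL Mapping from Bulk Segregant Sequencing with Smoothed G Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for QTL mapping by bulk segregant analysis
    (BSA) with short-read sequencing of pooled segregants. Computes the per-site
    G statistic on two-bulk allele-depth tables, its tricube kernel-smoothed
    version G' (Nadaraya-Watson regression with boundary reflection), theoretical
    null moments under the two-level hierarchical sampling model (binomial
    sampling of segregants into bulks, Poisson sampling of reads), log-normal
    tail p-values, a robust non-parametric null estimator (left median absolute
    deviation, Hampel outlier trimming, half-sample mode), Benjamini-Hochberg
    FDR region calling, and a full F2 truncation-selection simulator for null
    calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Genetics, Sequencing, StatisticalMethod, QualityControl
RoxygenNote: 7.3.3
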