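Package: fstase
Title: Gene-Level FST Selection Scans and Population-Scale Allele-Specific
    Expression Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale implementation of a two-layer screen for
    regulatory and genetic differentiation between livestock populations.
    Layer one computes per-SNP Weir-Cockerham fixation-index (FST) estimates
    between population pairs from diploid genotype calls, aggregates them per
    gene, standardizes gene means to Z(FST) scores, selects candidate genes,
    and colocalizes candidate-gene SNPs with quantitative-trait-locus (QTL)
    intervals by trait category. Layer two detects population-level
    allele-specific expression (ASE) per gene and strain-by-age group from
    unphased allelic read counts, using a folded binomial deviance statistic
    with an adaptive resampling null and Benjamini-Hochberg false-discovery
    control. A synthetic-data generator (Balding-Nichols genotypes, planted
    divergent genes, overdispersed allelic counts) provides ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
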