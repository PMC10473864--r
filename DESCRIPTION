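Package: asymlat
Title: Genetic and Evolutionary Analysis of Brain Left-Right Asymmetry Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genetics and evolution of left-right
    asymmetry in paired brain measurements. Constructs angular asymmetry
    traits from paired left/right phenotypes (signed and absolute, raw and
    standardized variants), performs genotype quality control, covariate
    residualization, per-SNP association scans with genomic-inflation
    diagnostics, greedy linkage-disequilibrium clumping into quantitative
    trait loci, and sparse genetic-relatedness pruning. Provides the three
    replication concordance indexes (sign concordance rate, effect-size
    correlation, Bonferroni-threshold QTL replication), interval-based
    SNP-to-gene assignment, clade-of-origin (gene age) enrichment with a
    stepwise binomial procedure, a cross-species Brain Specificity Index
    analysis, and a hemispheric expression asymmetry-level analysis. A
    synthetic-data module generates genotypes with local linkage
    disequilibrium, paired traits with known asymmetry QTLs, gene-age maps
    with planted enrichment, and expression tables with planted effects, so
    every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    rtracklayer,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
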