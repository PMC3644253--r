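Package: sleepqg
Title: Quantitative Genetics of Sleep in Inbred Line Panels
Version: 0.1.0
Authors@R: person("sleepqg", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative-genetic dissection of sleep phenotypes in
    panels of fully inbred lines measured with Drosophila activity monitors.
    Converts minute-binned beam-crossing streams into day/night sleep traits
    (duration, bout number, average bout length, waking activity), partitions
    phenotypic variance with REML mixed models to estimate broad-sense
    heritability of trait means and of the coefficient of environmental
    variation (CV_E), performs single-SNP genome-wide association with
    genotype-by-sex models and Benjamini-Hochberg FDR control, collapses
    significant sites in linkage-disequilibrium blocks and chromosomal
    inversions onto proxy SNPs, and fits iterative forward-selection additive
    multi-SNP models. A bundled synthetic-data generator emulates the design
    of an inbred reference panel (blocks, replicates, sexes, low-MAF-skewed
    site frequency spectrum, local LD, inversion karyotypes, and genetic
    variance in the environmental standard deviation) so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    lme4,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
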