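Package: growmark
Title: Growth-Associated and Population-Unique SNP Marker Discovery in
    Structured Fish Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-variant-calling analysis pipeline for identifying
    growth-associated and population-unique SNP markers in structured
    aquaculture populations. Starting from a multi-sample VCF of biallelic
    SNPs, the package applies quality-control filters (minor allele
    frequency, missingness, Hardy-Weinberg exact test), computes
    per-population diversity statistics (Ho, He, Pi, PIC), identity-by-state
    distances and neighbor-joining trees, adjusts phenotypes for population
    and environmental confounding with a genomic mixed model (GBLUP/REML),
    runs EMMAX-style mixed-linear-model GWAS with Bonferroni control,
    recovers non-tag linked SNPs inside annotated gene windows by
    linkage-disequilibrium r-squared, and classifies superior genotypes and
    population-unique markers by one-way ANOVA with LSD post-hoc tests.
    A synthetic-data generator with Balding-Nichols population divergence
    and Markov-chain linkage disequilibrium makes every stage testable
    without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
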