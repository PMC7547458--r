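Package: crossexpress
Title: Integrated eQTL, Allele-Specific Expression and Trait Correlation
    Analysis for F1-Cross RNA-seq Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for mapping expression quantitative
    trait loci (eQTL) with a covariate-adjusted linear model, calling
    allele-specific expression (ASE) from per-sample allele read counts with
    an exact binomial test and per-sample false discovery rate control, and
    integrating both with trait-expression correlations into a candidate-gene
    report. Includes genotype quality control (minor-allele-frequency,
    missingness and genotype-class-median filters, mode imputation,
    cross-platform concordance and heterozygote precision), rank-based
    inverse-normal expression normalization, REML heritability of expression
    from a genomic relationship matrix, EM-based linkage disequilibrium
    statistics, genomic inflation and eQTL pleiotropy summaries, and a
    synthetic-data generator that emulates an F1 cross of two divergent
    founder breeds with planted cis effects, allelic imbalance and gene-trait
    correlations so that every stage can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
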