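Package: gbsabc
Title: Population-Genomic Summaries and Coalescent ABC Demographic
    Inference for GBS SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diploid biallelic SNP matrices derived from
    genotyping-by-sequencing (GBS): VCF and population-map input/output,
    Stacks-style locus filtering, windowed linkage-disequilibrium pruning,
    group summary statistics (nucleotide diversity, observed
    heterozygosity, private alleles), fixed-allele-sharing classification
    among three groups, and likelihood-free demographic inference by
    approximate Bayesian computation: coalescent SNP simulation under
    divergence/admixture scenarios, rejection sampling with weighted
    local-linear regression adjustment, scenario choice by direct and
    multinomial-logistic estimators, and accuracy metrics for posterior
    estimates. Includes a synthetic-data generator that emulates the
    study designs the package targets, so every stage is testable with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
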