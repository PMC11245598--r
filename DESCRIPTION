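Package: denovotada
Title: De Novo Variant Burden and Bayesian Gene Association for Trio
    Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rare de novo variant analysis in parent-child trio
    whole-exome sequencing cohorts. Implements stringent trio-based de novo
    variant filtering (allele-balance, parental-absence, depth, and mapping
    quality gates, with X-chromosome rules for male and female probands),
    classification of variants by predicted damage (protein-truncating,
    MPC-damaging missense) and population rarity (gnomAD non-neuro allele
    frequency tiers), callable-exome haploid mutation rate estimation with
    exact Poisson confidence intervals, one-tailed exact rate-ratio tests
    between cases and controls, TADA-style Bayesian gene-level association
    combining de novo and independent case-control counts via Gamma-prior
    Bayes factors with Bayesian FDR q-values, and gene-set overlap and
    Fisher over-representation analysis. Includes a synthetic trio-cohort
    simulator so every stage of the pipeline can be exercised and validated
    without access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
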