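test_that("identical configuration and seed give identical cohorts", {
  cfg <- simulation_config(n_case_trios = 15, n_control_trios = 15,
                           gene_table = simulate_gene_table(60, seed = 2),
                           seed = 7)
  a <- simulate_trio_cohort(cfg)
  b <- simulate_trio_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$truth, b$truth)
  # a different seed gives a different cohort
  cfg2 <- simulation_config(n_case_trios = 15, n_control_trios = 15,
                            gene_table = simulate_gene_table(60, seed = 2),
                            seed = 8)
  expect_false(identical(simulate_trio_cohort(cfg2)$variants, a$variants))
})

test_that("null rates give empty cohorts and zero genes error", {
  gt <- simulate_gene_table(10, seed = 1)
  gt[, c("mu_ptv", "mu_misd", "mu_missense_other", "mu_synonymous")] <- 0
  cfg <- simulation_config(n_case_trios = 10, n_control_trios = 10,
                           gene_table = gt, inherited_rate = 0, seed = 3)
  coh <- simulate_trio_cohort(cfg)
  expect_equal(sum(coh$variants$true_denovo), 0)
  expect_equal(nrow(coh$variants), 0)

  expect_error(simulation_config(gene_table = gt[0, ]), "at least one")
})

test_that("de novo event counts are Poisson with mean 2 x haploid rate", {
  # 1000 trios at a total haploid rate of 1.0 per trio: the mean number of
  # true de novo events per trio must be within 3 standard errors of 2.0
  gt <- simulate_gene_table(
    200, class_totals = c(ptv = 0.25, misd = 0.25,
                          missense_other = 0.25, synonymous = 0.25),
    seed = 4)
  cfg <- simulation_config(n_case_trios = 0, n_control_trios = 1000,
                           gene_table = gt, risk_gene_fraction = 0,
                           inherited_rate = 0, seed = 11)
  coh <- simulate_trio_cohort(cfg)
  counts <- table(factor(coh$variants$family_id,
                         levels = unique(coh$pedigree$family_id)))
  m <- mean(counts)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(m - 2), 3 * se)
})

test_that("truth labels are conserved and true de novos carry alt reads", {
  cfg <- simulation_config(n_case_trios = 25, n_control_trios = 25,
                           gene_table = simulate_gene_table(80, seed = 5),
                           seed = 13)
  coh <- simulate_trio_cohort(cfg)
  expect_equal(sum(coh$truth$records$true_denovo),
               sum(coh$variants$true_denovo))
  expect_equal(nrow(coh$truth$records), nrow(coh$variants))
  dn <- coh$variants[coh$variants$true_denovo, ]
  expect_true(all(dn$ad_child > 0))
  expect_true(all(coh$variants$ad_child <= coh$variants$dp_child))
  expect_true(all(coh$variants$ad_mother <= coh$variants$dp_mother))
  # inherited variants carry alt reads in at least one parent
  inh <- coh$variants[!coh$variants$true_denovo, ]
  expect_true(all(inh$ad_mother + inh$ad_father > 0))
})

test_that("male-X de novo variants are near-hemizygous", {
  gt <- simulate_gene_table(100, x_fraction = 0.5, seed = 6)
  cfg <- simulation_config(n_case_trios = 60, n_control_trios = 0,
                           gene_table = gt, inherited_rate = 0,
                           prob_male = 1, seed = 17)
  coh <- simulate_trio_cohort(cfg)
  x_dn <- coh$variants[coh$variants$chrom == "chrX" &
                         coh$variants$true_denovo, ]
  expect_gt(nrow(x_dn), 0)
  af <- x_dn$ad_child / x_dn$dp_child
  expect_gt(median(af), 0.85)
})

test_that("case-control counts follow the TADA generative model", {
  gt <- simulate_gene_table(4000, seed = 7)
  hyper <- tada_hyperparameters()

  # null table: the case share of counts centers on n_cases / total
  null_tab <- simulate_case_control_counts(gt, 3206, 5002, hyper,
                                           pi_sim = 0, seed = 21)
  expect_false(any(null_tab$is_risk))
  share <- sum(null_tab$x_ca_ptv) /
    sum(null_tab$x_ca_ptv + null_tab$x_co_ptv)
  expect_lt(abs(share - 3206 / 8208), 0.03)

  # a degenerate gamma = 1 prior behaves like the null
  hyper1 <- tada_hyperparameters(gamma_cc_ptv = 1, beta_cc_ptv = 1e6,
                                 gamma_cc_misd = 1, beta_cc_misd = 1e6)
  tab1 <- simulate_case_control_counts(gt, 3206, 5002, hyper1,
                                       pi_sim = 0.5, seed = 22)
  share1 <- sum(tab1$x_ca_ptv) / sum(tab1$x_ca_ptv + tab1$x_co_ptv)
  expect_lt(abs(share1 - 3206 / 8208), 0.03)

  # risk-gene case counts exceed non-risk in expectation by gamma_mean
  tab <- simulate_case_control_counts(gt, 3206, 5002, hyper,
                                      pi_sim = 0.05, seed = 23,
                                      baseline_multiplier = 200)
  mean_rate_risk <- sum(tab$x_ca_ptv[tab$is_risk]) /
    sum(gt$mu_ptv[tab$is_risk])
  mean_rate_null <- sum(tab$x_ca_ptv[!tab$is_risk]) /
    sum(gt$mu_ptv[!tab$is_risk])
  ratio <- mean_rate_risk / mean_rate_null
  # analytic expectation of the enrichment ratio is gamma_mean = 1.78;
  # allow Monte-Carlo spread
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 2.4)

  expect_error(simulate_case_control_counts(gt, 0, 100, hyper), "positive")
})

test_that("simulated cohorts round-trip through the on-disk formats", {
  cfg <- simulation_config(n_case_trios = 5, n_control_trios = 4,
                           gene_table = simulate_gene_table(40, seed = 9),
                           seed = 29)
  coh <- simulate_trio_cohort(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  ped <- withr::local_tempfile(fileext = ".ped")
  cov <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_vcf(coh$variants, coh$pedigree, vcf)
  write_pedigree(coh$pedigree, ped)
  write_coverage_table(coh$coverage, cov)

  ped2 <- read_pedigree(ped)
  expect_setequal(ped2$member_id, coh$pedigree$member_id)

  cov2 <- read_coverage_table(cov)
  expect_equal(cov2$callable_bp, coh$coverage$callable_bp)

  v2 <- read_trio_variants(vcf, ped2)
  carried <- coh$variants[coh$variants$ad_child > 0, ]
  expect_equal(nrow(v2), nrow(carried))
  key <- function(x) paste(x$family_id, x$chrom, x$pos, x$alt_allele)
  expect_setequal(key(v2), key(carried))
  m <- match(key(carried), key(v2))
  expect_equal(v2$ad_child[m], carried$ad_child)
  expect_equal(v2$consequence[m], carried$consequence)
  expect_equal(v2$gnomad_nonneuro_af[m], carried$gnomad_nonneuro_af,
               tolerance = 1e-6)
  # positions come back on the same 1-based coordinate system
  expect_equal(sort(v2$pos), sort(carried$pos))
})
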