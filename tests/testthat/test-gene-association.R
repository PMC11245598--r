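test_that("de novo Bayes factor matches numerical quadrature on a grid", {
  quad_bf <- function(x, n_trio, mu, gamma_mean, beta) {
    lambda0 <- 2 * n_trio * mu
    h1 <- stats::integrate(function(g) {
      dpois(x, lambda0 * g) * dgamma(g, shape = gamma_mean * beta,
                                     rate = beta)
    }, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-300)$value
    h1 / dpois(x, lambda0)
  }
  hyper <- tada_hyperparameters()
  grid <- expand.grid(x = c(0, 1, 2, 5, 10),
                      mu = c(1e-7, 1e-6, 1e-5, 1e-4),
                      cat = c("PTV", "MisD"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    pr <- hyper$dn[[grid$cat[i]]]
    got <- denovo_bf(grid$x[i], 147, grid$mu[i],
                     pr[["gamma_mean"]], pr[["beta"]])
    want <- quad_bf(grid$x[i], 147, grid$mu[i],
                    pr[["gamma_mean"]], pr[["beta"]])
    expect_equal(got, want, tolerance = 1e-8, label = paste0(
      "BF(x=", grid$x[i], ", mu=", grid$mu[i], ", ", grid$cat[i], ")"))
  }
})

test_that("de novo Bayes factor limiting behavior", {
  # degenerate prior at gamma = 1 makes the two hypotheses identical
  for (x in 0:5) {
    expect_equal(denovo_bf(x, 147, 1e-5, gamma_mean = 1, beta = 1e9), 1,
                 tolerance = 1e-3)
  }
  # an enrichment prior is penalized by a zero count
  expect_lt(denovo_bf(0, 147, 1e-5, 21.35, 0.82), 1)
  # mu = 0 conventions
  expect_equal(denovo_bf(0, 147, 0, 21.35, 0.82), 1)
  expect_gt(denovo_bf(1, 147, 0, 21.35, 0.82), 1)  # rate floor applies
  # strictly increasing in the count
  bf <- denovo_bf(0:8, 147, 1e-5, 21.35, 0.82)
  expect_true(all(diff(bf) > 0))
})

test_that("case-control Bayes factor matches fine-grid integration", {
  grid_bf <- function(x_ca, x_co, n_ca, n_co, gamma_mean, beta) {
    n <- x_ca + x_co
    g <- seq(1e-9, 80, length.out = 4e5)
    h1 <- sum(dbinom(x_ca, n, n_ca * g / (n_ca * g + n_co)) *
                dgamma(g, gamma_mean * beta, rate = beta)) * (g[2] - g[1])
    h1 / dbinom(x_ca, n, n_ca / (n_ca + n_co))
  }
  cases <- rbind(c(6, 1), c(2, 2), c(0, 3), c(10, 4))
  for (i in seq_len(nrow(cases))) {
    got <- case_control_bf(cases[i, 1], cases[i, 2], 3206, 5002, 1.78, 3.98)
    want <- grid_bf(cases[i, 1], cases[i, 2], 3206, 5002, 1.78, 3.98)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # no data and degenerate prior both give BF 1
  expect_equal(case_control_bf(0, 0, 3206, 5002, 1.78, 3.98), 1)
  expect_equal(case_control_bf(4, 3, 3206, 5002, gamma_mean = 1,
                               beta = 1e9), 1, tolerance = 1e-3)
})

test_that("Bayesian FDR is the running mean of (1 - PP), with tied q", {
  expect_equal(bayesian_fdr(c(0.96, 0.90, 0.50)),
               c(0.04, 0.07, 0.64 / 3))
  expect_equal(bayesian_fdr(1), 0)
  # order of input does not matter
  expect_equal(bayesian_fdr(c(0.50, 0.96, 0.90)),
               c(0.64 / 3, 0.04, 0.07))
  # ties share the q of the last tied rank
  q <- bayesian_fdr(c(0.9, 0.9, 0.4))
  expect_equal(q[1], q[2])
  expect_equal(q[1], mean(c(0.1, 0.1)))
  # q is nondecreasing along the PP ranking
  set.seed(99)
  pp <- runif(50)
  q <- bayesian_fdr(pp)
  expect_true(all(diff(q[order(pp, decreasing = TRUE)]) >= -1e-12))
})

test_that("gene posteriors combine categories and assign tiers", {
  hyper <- tada_hyperparameters()
  ev <- tibble::tibble(
    gene = c("NULLGENE", "HITGENE"),
    mu_ptv = c(1e-6, 1e-6), mu_misd = c(1e-6, 1e-6),
    x_dn_ptv = c(0L, 3L), x_dn_misd = c(0L, 0L),
    x_ca_ptv = c(0L, 6L), x_co_ptv = c(0L, 0L),
    x_ca_misd = c(0L, 0L), x_co_misd = c(0L, 0L))
  res <- combine_and_posterior(ev, n_trio = 147, n_case = 3206,
                               n_control = 5002, hyper = hyper)
  expect_equal(res$gene[1], "HITGENE")
  hit <- res[res$gene == "HITGENE", ]
  expect_equal(hit$bf_total,
               hit$bf_dn_ptv * hit$bf_dn_misd * hit$bf_cc_ptv *
                 hit$bf_cc_misd)
  expect_equal(hit$pp,
               hyper$pi * hit$bf_total / (hyper$pi * hit$bf_total + 1 -
                                            hyper$pi))
  expect_equal(hit$tier, "high_confidence")

  # a gene whose categories are all BF 1 keeps the prior
  nul <- res[res$gene == "NULLGENE", ]
  expect_lt(abs(nul$pp - hyper$pi), 0.02)

  expect_error(combine_and_posterior(
    tibble::tibble(gene = c("A", "A"), mu_ptv = 1e-6, mu_misd = 1e-6),
    147, 3206, 5002), "duplicate")
})

test_that("risk gene count rounds pi times the universe size", {
  expect_equal(risk_gene_count(0.5, 100), 50L)
  expect_equal(risk_gene_count(0.055, 19560), 1076L)
  expect_equal(risk_gene_count(0, 19560), 0L)
})

test_that("the ACMG exclusion shapes the gene universe", {
  acmg <- acmg_genes()
  expect_length(acmg, 58)
  expect_true("BRCA1" %in% acmg)
  universe <- c("KDM5B", "BRCA1", "STAG1", "TP53")
  kept <- suppressWarnings(build_gene_universe(universe))
  expect_setequal(kept, c("KDM5B", "STAG1"))
  # empty exclusion list is the identity
  expect_setequal(build_gene_universe(universe, exclude = character()),
                  universe)
  # absent exclusion symbols warn but do not error
  expect_warning(build_gene_universe(c("KDM5B"), exclude = c("ZZZ9")),
                 "not present")
})

test_that("true risk genes rank above non-risk genes on synthetic data", {
  hyper <- tada_hyperparameters()
  gt <- simulate_gene_table(1500, seed = 31)
  set.seed(32)
  is_risk <- runif(nrow(gt)) < hyper$pi
  dn_draw <- function(mu, prior) {
    gam <- rep(1, nrow(gt))
    gam[is_risk] <- rgamma(sum(is_risk),
                           shape = prior[["gamma_mean"]] * prior[["beta"]],
                           rate = prior[["beta"]])
    rpois(nrow(gt), 2 * 1000 * mu * gam)
  }
  x_ptv <- dn_draw(gt$mu_ptv, hyper$dn$PTV)
  x_misd <- dn_draw(gt$mu_misd, hyper$dn$MisD)
  cc <- simulate_case_control_counts(gt, 3206, 5002, hyper, seed = 33,
                                     risk_genes = gt$gene[is_risk])
  ev <- tibble::tibble(gene = gt$gene, mu_ptv = gt$mu_ptv,
                       mu_misd = gt$mu_misd,
                       x_dn_ptv = x_ptv, x_dn_misd = x_misd,
                       x_ca_ptv = cc$x_ca_ptv, x_co_ptv = cc$x_co_ptv,
                       x_ca_misd = cc$x_ca_misd, x_co_misd = cc$x_co_misd)
  res <- combine_and_posterior(ev, 1000, 3206, 5002, hyper)
  res$is_risk <- is_risk[match(res$gene, gt$gene)]
  expect_gt(median(res$pp[res$is_risk]), median(res$pp[!res$is_risk]))
})
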