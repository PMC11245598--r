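# Synthetic trio cohorts with the statistical structure the downstream
# analysis assumes: Poisson de novo events at per-gene haploid rates
# (inflated in risk genes of case trios), read-depth/allele-fraction noise,
# inherited variants, per-trio callable coverage, and case-control count
# tables drawn from the TADA generative model.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic per-gene mutation-rate table
#'
#' Draws per-gene haploid de novo mutation rates for the PTV, damaging
#' missense (MisD), other-missense and synonymous classes. Gene-to-gene
#' variation is log-uniform over two orders of magnitude, then each class is
#' rescaled so the class totals match exome-scale expectations (defaults:
#' summed haploid rates 0.045 PTV, 0.02 MisD, 0.37 other missense, 0.17
#' synonymous, i.e. roughly 1.2 coding de novo variants per child). A small
#' fraction of genes is placed on chromosome X so sex-specific logic can be
#' exercised.
#'
#' @param n_genes Number of genes.
#' @param class_totals Named numeric vector of summed haploid rates for
#'   `ptv`, `misd`, `missense_other`, `synonymous`.
#' @param x_fraction Fraction of genes assigned to chromosome X.
#' @param seed Integer seed.
#' @return A tibble with `gene`, `chrom`, and `mu_ptv`, `mu_misd`,
#'   `mu_missense_other`, `mu_synonymous`.
#' @export
simulate_gene_table <- function(n_genes = 500,
                                class_totals = c(ptv = 0.045, misd = 0.02,
                                                 missense_other = 0.37,
                                                 synonymous = 0.17),
                                x_fraction = 0.04, seed = 1) {
  stopifnot(n_genes >= 1, all(class_totals >= 0))
  with_seed(seed, {
    base <- 10^stats::runif(n_genes, -2, 0)
    jitter <- function() base * 10^stats::runif(n_genes, -0.2, 0.2)
    tab <- tibble::tibble(
      gene = sprintf("GENE%04d", seq_len(n_genes)),
      chrom = ifelse(stats::runif(n_genes) < x_fraction, "chrX",
                     paste0("chr", sample(1:22, n_genes, replace = TRUE))),
      mu_ptv = jitter(), mu_misd = jitter(),
      mu_missense_other = jitter(), mu_synonymous = jitter()
    )
    tab$mu_ptv <- tab$mu_ptv / sum(tab$mu_ptv) * class_totals[["ptv"]]
    tab$mu_misd <- tab$mu_misd / sum(tab$mu_misd) * class_totals[["misd"]]
    tab$mu_missense_other <- tab$mu_missense_other /
      sum(tab$mu_missense_other) * class_totals[["missense_other"]]
    tab$mu_synonymous <- tab$mu_synonymous / sum(tab$mu_synonymous) *
      class_totals[["synonymous"]]
    tab
  })
}

#' Simulation configuration for synthetic trio cohorts
#'
#' Collects every generative parameter of the cohort simulator. The seed
#' fully determines the output.
#'
#' @param n_case_trios,n_control_trios Trio counts (defaults 147 / 780, the
#'   post-QC sizes of the emulated study design).
#' @param gene_table Per-gene haploid mutation rates per class (see
#'   [simulate_gene_table()]).
#' @param risk_gene_fraction Proportion of genes that are risk genes
#'   (default 0.055).
#' @param relative_risk Named numeric vector of de novo relative-risk
#'   multipliers applied to risk genes in case trios, per class (defaults:
#'   PTV 21.35, MisD 20.34, others 1).
#' @param inherited_rate Mean number of simulated inherited (parental)
#'   variant sites per trio (default 5; kept small because inherited
#'   variation only serves to exercise the parental-absence gates).
#' @param depth_mean,depth_size Negative-binomial per-site read depth model
#'   (mean and size/overdispersion; defaults 60 and 10).
#' @param mq_mean,mq_sd Gaussian mapping-quality model (defaults 60, 3).
#' @param het_af_shape Shape of the symmetric Beta distribution for true
#'   heterozygous allele fractions (default 20, i.e. Beta(20, 20) around
#'   0.5, so a small tail falls outside the 0.3-0.7 gate).
#' @param parent_error_af Mean parental alternate-read contamination /
#'   error fraction at true de novo sites (default 0.005).
#' @param denovo_af_spike_prob Probability a true de novo variant has a
#'   small nonzero gnomAD non-neuro frequency instead of 0 (default 0.125,
#'   matching the observed mix of 0 and ~3e-5 values).
#' @param denovo_af_spike_range Range of the nonzero spike (default
#'   1e-5 to 5e-5, straddling the ultra-rare boundary region).
#' @param inherited_af_range Log10 range of gnomAD frequencies for
#'   inherited variants (default 1e-6 to 1e-2).
#' @param callable_bp_mean,callable_bp_sd Per-trio callable coverage model
#'   (defaults 3e7 and 2e6, an exome capture intersection scale).
#' @param prob_male Probability the child is male (default 0.5).
#' @param seed Integer seed.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_case_trios = 147, n_control_trios = 780,
                              gene_table = simulate_gene_table(),
                              risk_gene_fraction = 0.055,
                              relative_risk = c(ptv = 21.35, misd = 20.34,
                                                missense_other = 1,
                                                synonymous = 1),
                              inherited_rate = 5,
                              depth_mean = 60, depth_size = 10,
                              mq_mean = 60, mq_sd = 3,
                              het_af_shape = 20,
                              parent_error_af = 0.005,
                              denovo_af_spike_prob = 0.125,
                              denovo_af_spike_range = c(1e-5, 5e-5),
                              inherited_af_range = c(1e-6, 1e-2),
                              callable_bp_mean = 3e7, callable_bp_sd = 2e6,
                              prob_male = 0.5, seed = 1) {
  if (nrow(gene_table) == 0) {
    stop("gene_table must contain at least one gene", call. = FALSE)
  }
  stopifnot(n_case_trios >= 0, n_control_trios >= 0,
            risk_gene_fraction >= 0, risk_gene_fraction < 1,
            all(relative_risk >= 0), inherited_rate >= 0,
            depth_mean > 0, depth_size > 0, het_af_shape > 0,
            parent_error_af >= 0, parent_error_af < 1,
            callable_bp_mean > 0, prob_male >= 0, prob_male <= 1)
  mu_cols <- c("mu_ptv", "mu_misd", "mu_missense_other", "mu_synonymous")
  if (!all(mu_cols %in% names(gene_table)) ||
      any(vapply(mu_cols, function(cl) any(gene_table[[cl]] < 0), TRUE))) {
    stop("gene_table must have nonnegative ", paste(mu_cols, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_case_trios = n_case_trios, n_control_trios = n_control_trios,
         gene_table = gene_table, risk_gene_fraction = risk_gene_fraction,
         relative_risk = relative_risk, inherited_rate = inherited_rate,
         depth_mean = depth_mean, depth_size = depth_size,
         mq_mean = mq_mean, mq_sd = mq_sd, het_af_shape = het_af_shape,
         parent_error_af = parent_error_af,
         denovo_af_spike_prob = denovo_af_spike_prob,
         denovo_af_spike_range = denovo_af_spike_range,
         inherited_af_range = inherited_af_range,
         callable_bp_mean = callable_bp_mean,
         callable_bp_sd = callable_bp_sd,
         prob_male = prob_male, seed = seed),
    class = "simulation_config"
  )
}

sim_classes <- function() c("ptv", "misd", "missense_other", "synonymous")

# draw a consequence / MPC pair for a variant of a given simulation class
sim_consequence <- function(class, n) {
  cons <- switch(class,
                 ptv = sample(c("stopgain", "frameshift_insertion",
                                "frameshift_deletion", "canonical_splice"),
                              n, replace = TRUE),
                 misd = rep("missense", n),
                 missense_other = rep("missense", n),
                 synonymous = rep("synonymous", n))
  mpc <- switch(class,
                misd = stats::runif(n, 2.01, 4),
                missense_other = ifelse(stats::runif(n) < 0.8,
                                        stats::runif(n, 0, 2), NA_real_),
                rep(NA_real_, n))
  list(consequence = cons, mpc = mpc)
}

rdepth <- function(n, config) {
  pmax(1L, stats::rnbinom(n, mu = config$depth_mean, size = config$depth_size))
}

rmq <- function(n, config) {
  pmin(93, pmax(0, stats::rnorm(n, config$mq_mean, config$mq_sd)))
}

#' Simulate a parent-child trio cohort
#'
#' Generates case and control trios. Per trio and variant class, the number
#' of true de novo events is Poisson with mean twice the summed per-gene
#' haploid rate (two haplotypes per child), with events placed in genes
#' proportionally to their rates; in case trios, risk genes have their rate
#' multiplied by the class relative risk. Inherited variant sites are
#' present heterozygously in exactly one parent and transmitted to the child
#' with probability 1/2. Every record carries read depths, alternate
#' depths and mapping qualities from the configured noise models; true de
#' novo variants on chromosome X in male children are hemizygous with
#' near-1 allele fraction.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `"simulated_cohort"` with `variants` (variant
#'   records plus `record_id`, `group` and `true_denovo`), `pedigree`,
#'   `coverage`, and `truth` (risk genes and per-record labels).
#' @export
simulate_trio_cohort <- function(config) {
  gt <- config$gene_table
  with_seed(config$seed, {
    risk <- stats::runif(nrow(gt)) < config$risk_gene_fraction
    risk_genes <- gt$gene[risk]

    fam <- c(if (config$n_case_trios > 0)
               sprintf("case%03d", seq_len(config$n_case_trios)),
             if (config$n_control_trios > 0)
               sprintf("ctrl%03d", seq_len(config$n_control_trios)))
    group <- rep(c("case", "control"),
                 c(config$n_case_trios, config$n_control_trios))
    sex <- ifelse(stats::runif(length(fam)) < config$prob_male,
                  "male", "female")

    pedigree <- tibble::tibble(
      family_id = rep(fam, each = 3),
      member_id = paste0(rep(fam, each = 3), c(".p1", ".mo", ".fa")),
      role = rep(c("child", "mother", "father"), length(fam)),
      sex = as.vector(rbind(sex, "female", "male")),
      affected = rep(group == "case", each = 3) &
        rep(c(TRUE, FALSE, FALSE), length(fam))
    )

    coverage <- tibble::tibble(
      family_id = fam,
      callable_bp = round(pmax(
        config$callable_bp_mean / 10,
        stats::rnorm(length(fam), config$callable_bp_mean,
                     config$callable_bp_sd)))
    )

    # --- true de novo events ------------------------------------------------
    events <- list()
    for (class in sim_classes()) {
      mu <- gt[[paste0("mu_", class)]]
      mu_case <- mu * ifelse(risk, config$relative_risk[[class]], 1)
      lambda <- ifelse(group == "case", 2 * sum(mu_case), 2 * sum(mu))
      n_events <- stats::rpois(length(fam), lambda)
      total <- sum(n_events)
      if (total == 0) next
      trio_idx <- rep(seq_along(fam), n_events)
      gene_idx <- integer(total)
      is_case <- group[trio_idx] == "case"
      if (any(is_case) && sum(mu_case) > 0) {
        gene_idx[is_case] <- sample(nrow(gt), sum(is_case), replace = TRUE,
                                    prob = mu_case)
      }
      if (any(!is_case) && sum(mu) > 0) {
        gene_idx[!is_case] <- sample(nrow(gt), sum(!is_case), replace = TRUE,
                                     prob = mu)
      }
      ann <- sim_consequence(class, total)
      events[[class]] <- tibble::tibble(
        trio = trio_idx, gene_idx = gene_idx,
        consequence = ann$consequence, mpc = ann$mpc,
        class = class, true_denovo = TRUE)
    }

    # --- inherited variant sites -------------------------------------------
    n_inh <- stats::rpois(length(fam), config$inherited_rate)
    inherited <- NULL
    if (sum(n_inh) > 0) {
      total <- sum(n_inh)
      mu_all <- gt$mu_ptv + gt$mu_misd + gt$mu_missense_other +
        gt$mu_synonymous
      class_probs <- c(sum(gt$mu_ptv), sum(gt$mu_misd),
                       sum(gt$mu_missense_other), sum(gt$mu_synonymous))
      cls <- sample(sim_classes(), total, replace = TRUE, prob = class_probs)
      anns <- lapply(sim_classes(), function(cl) sim_consequence(cl, total))
      names(anns) <- sim_classes()
      pick <- match(cls, sim_classes())
      inherited <- tibble::tibble(
        trio = rep(seq_along(fam), n_inh),
        gene_idx = sample(nrow(gt), total, replace = TRUE, prob = mu_all),
        consequence = vapply(seq_len(total), function(i)
          anns[[pick[i]]]$consequence[i], ""),
        mpc = vapply(seq_len(total), function(i)
          anns[[pick[i]]]$mpc[i], 0),
        class = cls, true_denovo = FALSE)
    }

    ev <- dplyr::bind_rows(c(events, list(inherited = inherited)))
    if (nrow(ev) == 0) {
      return(structure(list(variants = empty_cohort_variants(),
                            pedigree = pedigree, coverage = coverage,
                            truth = list(risk_genes = risk_genes,
                                         records = tibble::tibble(
                                           record_id = integer(),
                                           true_denovo = logical()))),
                       class = "simulated_cohort"))
    }

    n <- nrow(ev)
    chrom <- gt$chrom[ev$gene_idx]
    male_x <- chrom == "chrX" & sex[ev$trio] == "male"

    dp_child <- rdepth(n, config)
    dp_mother <- rdepth(n, config)
    dp_father <- rdepth(n, config)

    # child allele fraction: het Beta(s, s); hemizygous male-X near 1
    af_child <- stats::rbeta(n, config$het_af_shape, config$het_af_shape)
    af_child[male_x & ev$true_denovo] <-
      stats::rbeta(sum(male_x & ev$true_denovo), 40, 2)
    af_err <- config$parent_error_af

    ad_child <- integer(n)
    ad_mother <- integer(n)
    ad_father <- integer(n)

    dn <- ev$true_denovo
    # de novo: child carries, parents at error rate (guarantee child alt > 0)
    ad_child[dn] <- pmax(1L, stats::rbinom(sum(dn), dp_child[dn],
                                           af_child[dn]))
    ad_mother[dn] <- stats::rbinom(sum(dn), dp_mother[dn], af_err)
    ad_father[dn] <- stats::rbinom(sum(dn), dp_father[dn], af_err)

    # inherited: exactly one parent het, transmitted with probability 1/2
    if (any(!dn)) {
      idx <- which(!dn)
      from_mother <- stats::runif(length(idx)) < 0.5
      af_parent <- stats::rbeta(length(idx), config$het_af_shape,
                                config$het_af_shape)
      ad_mother[idx] <- ifelse(
        from_mother,
        pmax(1L, stats::rbinom(length(idx), dp_mother[idx], af_parent)),
        stats::rbinom(length(idx), dp_mother[idx], af_err))
      ad_father[idx] <- ifelse(
        !from_mother,
        pmax(1L, stats::rbinom(length(idx), dp_father[idx], af_parent)),
        stats::rbinom(length(idx), dp_father[idx], af_err))
      transmitted <- stats::runif(length(idx)) < 0.5
      ad_child[idx] <- ifelse(
        transmitted,
        stats::rbinom(length(idx), dp_child[idx], af_child[idx]),
        stats::rbinom(length(idx), dp_child[idx], af_err))
    }

    # gnomAD non-neuro AF
    af_pop <- numeric(n)
    spike <- dn & stats::runif(n) < config$denovo_af_spike_prob
    af_pop[spike] <- stats::runif(sum(spike),
                                  config$denovo_af_spike_range[1],
                                  config$denovo_af_spike_range[2])
    if (any(!dn)) {
      lr <- log10(config$inherited_af_range)
      af_pop[!dn] <- 10^stats::runif(sum(!dn), lr[1], lr[2])
    }

    # synthetic coordinates: one 10-kb block per gene
    pos <- 10000L * ev$gene_idx +
      as.integer(sample.int(9999L, n, replace = TRUE))

    variants <- tibble::tibble(
      record_id = seq_len(n),
      family_id = fam[ev$trio],
      group = group[ev$trio],
      chrom = chrom,
      pos = pos,
      ref_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      gene = gt$gene[ev$gene_idx],
      consequence = ev$consequence,
      mpc = ev$mpc,
      gnomad_nonneuro_af = af_pop,
      child_sex = sex[ev$trio],
      dp_child = dp_child, ad_child = pmin(ad_child, dp_child),
      mq_child = rmq(n, config),
      dp_mother = dp_mother, ad_mother = pmin(ad_mother, dp_mother),
      mq_mother = rmq(n, config),
      dp_father = dp_father, ad_father = pmin(ad_father, dp_father),
      mq_father = rmq(n, config),
      evaluable = TRUE,
      true_denovo = dn,
      sim_class = ev$class
    )
    # avoid identical ref/alt
    same <- variants$ref_allele == variants$alt_allele
    variants$alt_allele[same] <- chartr("ACGT", "CGTA",
                                        variants$ref_allele[same])

    structure(
      list(variants = variants, pedigree = pedigree, coverage = coverage,
           truth = list(risk_genes = risk_genes,
                        records = variants[, c("record_id", "true_denovo")])),
      class = "simulated_cohort")
  })
}

empty_cohort_variants <- function() {
  v <- empty_variant_records()
  tibble::add_column(v, record_id = integer(), .before = 1) |>
    tibble::add_column(group = character(), .after = "record_id") |>
    tibble::add_column(true_denovo = logical(), sim_class = character())
}

#' @method print simulated_cohort
#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:",
      length(unique(x$pedigree$family_id)), "trios,",
      nrow(x$variants), "variant records (",
      sum(x$variants$true_denovo), "true de novo )\n")
  invisible(x)
}

#' Simulate per-gene case-control counts from the TADA generative model
#'
#' For every gene and category (PTV, MisD), control counts are Poisson with
#' rate `n_controls * q_g` and case counts Poisson with rate
#' `n_cases * q_g * gamma_g`, where the per-gene baseline `q_g` is
#' proportional to the gene's mutation rate and `gamma_g = 1` for non-risk
#' genes while risk genes draw `gamma_g` from the category's
#' Gamma(shape `gamma_mean * beta`, rate `beta`) prior.
#'
#' @param gene_table Per-gene rate table (see [simulate_gene_table()]).
#' @param n_cases,n_controls Sample sizes (positive).
#' @param hyper A [tada_hyperparameters()] object supplying the risk-gene
#'   relative-risk priors for the `cc` categories.
#' @param pi_sim Proportion of risk genes; set 0 for a null table.
#' @param seed Integer seed.
#' @param baseline_multiplier Scales mutation rates into per-individual
#'   carrier rates, `q_g = mu_g * baseline_multiplier` (default 20).
#' @param risk_genes Optional character vector fixing which genes are risk
#'   genes (overrides `pi_sim` sampling), e.g. to share truth labels with a
#'   trio simulation on the same `gene_table`.
#' @return A tibble with `gene`, counts `x_ca_ptv`, `x_co_ptv`, `x_ca_misd`,
#'   `x_co_misd`, `is_risk`, and the drawn `gamma_ptv`, `gamma_misd`.
#' @export
simulate_case_control_counts <- function(gene_table, n_cases, n_controls,
                                         hyper = tada_hyperparameters(),
                                         pi_sim = 0.055, seed = 1,
                                         baseline_multiplier = 20,
                                         risk_genes = NULL) {
  if (n_cases <= 0 || n_controls <= 0) {
    stop("sample sizes must be positive", call. = FALSE)
  }
  stopifnot(pi_sim >= 0, pi_sim < 1)
  n_genes <- nrow(gene_table)
  with_seed(seed, {
    if (is.null(risk_genes)) {
      is_risk <- stats::runif(n_genes) < pi_sim
    } else {
      is_risk <- gene_table$gene %in% risk_genes
    }
    draw <- function(mu_col, prior) {
      q <- gene_table[[mu_col]] * baseline_multiplier
      gamma <- rep(1, n_genes)
      if (any(is_risk)) {
        gamma[is_risk] <- stats::rgamma(
          sum(is_risk), shape = prior[["gamma_mean"]] * prior[["beta"]],
          rate = prior[["beta"]])
      }
      list(x_ca = stats::rpois(n_genes, n_cases * q * gamma),
           x_co = stats::rpois(n_genes, n_controls * q),
           gamma = gamma)
    }
    ptv <- draw("mu_ptv", hyper$cc$PTV)
    misd <- draw("mu_misd", hyper$cc$MisD)
    tibble::tibble(
      gene = gene_table$gene,
      x_ca_ptv = ptv$x_ca, x_co_ptv = ptv$x_co,
      x_ca_misd = misd$x_ca, x_co_misd = misd$x_co,
      is_risk = is_risk,
      gamma_ptv = ptv$gamma, gamma_misd = misd$gamma
    )
  })
}

#' Write cohort pedigree to a 6-column PED file
#'
#' @param pedigree Pedigree tibble (e.g. from [simulate_trio_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  fams <- split(pedigree, pedigree$family_id)
  lines <- unlist(lapply(fams, function(fam) {
    child <- fam[fam$role == "child", ]
    mother <- fam[fam$role == "mother", ]
    father <- fam[fam$role == "father", ]
    sex_code <- function(s) ifelse(s == "male", 1L, 2L)
    pheno <- function(a) ifelse(a, 2L, 1L)
    c(paste(fam$family_id[1], child$member_id, father$member_id,
            mother$member_id, sex_code(child$sex), pheno(child$affected)),
      paste(fam$family_id[1], father$member_id, 0, 0, 1,
            pheno(father$affected)),
      paste(fam$family_id[1], mother$member_id, 0, 0, 2,
            pheno(mother$affected)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-family coverage table
#'
#' @param coverage Tibble with `family_id` and `callable_bp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(coverage, path) {
  utils::write.table(coverage[, c("family_id", "callable_bp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cohort variant records as a multi-sample VCF
#'
#' Emits a VCF 4.2 file with per-sample GT:DP:AD:MQ fields for every member
#' of every trio in the pedigree and ANNOVAR-style INFO annotations (gene,
#' consequence, MPC, gnomAD non-neuro AF). Samples not involved in a record
#' are written as homozygous reference with nominal depth.
#'
#' @param variants Variant record tibble (e.g. from
#'   [simulate_trio_cohort()]).
#' @param pedigree Matching pedigree tibble.
#' @param path Output path.
#' @param tags Annotation tag configuration ([annotation_tags()]).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, pedigree, path,
                             tags = annotation_tags()) {
  samples <- pedigree$member_id
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">",
            tags$gene),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence\">",
            tags$consequence),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"MPC score\">",
            tags$mpc),
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,",
                   "Description=\"gnomAD non-neuro AF\">"), tags$gnomad_af),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  v <- variants[order(variants$chrom, variants$pos), ]
  ped_by_fam <- split(pedigree, pedigree$family_id)
  default_gt <- "0/0:30:30,0:60"
  fmt <- function(ad, dp, mq, gt) {
    sprintf("%s:%d:%d,%d:%.1f", gt, dp, dp - ad, ad, mq)
  }
  body <- vapply(seq_len(nrow(v)), function(i) {
    rec <- v[i, ]
    info <- paste0(
      tags$gene, "=", rec$gene, ";",
      tags$consequence, "=", rec$consequence, ";",
      if (!is.na(rec$mpc)) paste0(tags$mpc, "=", rec$mpc, ";") else "",
      tags$gnomad_af, "=", format(rec$gnomad_nonneuro_af, scientific = TRUE))
    fam <- ped_by_fam[[rec$family_id]]
    gts <- stats::setNames(rep(default_gt, length(samples)), samples)
    gt_of <- function(ad, dp) {
      if (ad == 0) "0/0" else if (ad == dp) "1/1" else "0/1"
    }
    gts[fam$member_id[fam$role == "child"]] <-
      fmt(rec$ad_child, rec$dp_child, rec$mq_child,
          gt_of(rec$ad_child, rec$dp_child))
    gts[fam$member_id[fam$role == "mother"]] <-
      fmt(rec$ad_mother, rec$dp_mother, rec$mq_mother,
          gt_of(rec$ad_mother, rec$dp_mother))
    gts[fam$member_id[fam$role == "father"]] <-
      fmt(rec$ad_father, rec$dp_father, rec$mq_father,
          gt_of(rec$ad_father, rec$dp_father))
    paste(c(rec$chrom, rec$pos, ".", rec$ref_allele, rec$alt_allele, ".",
            "PASS", info, "GT:DP:AD:MQ", gts), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
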