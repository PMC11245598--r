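test_that("allele fractions and unevaluable depth sentinels", {
  expect_equal(allele_fraction(15, 30), 0.5)
  expect_equal(allele_fraction(0, 25), 0)
  expect_equal(allele_fraction(7, 20), 0.35)
  expect_true(is.na(allele_fraction(3, 0)))
  expect_equal(allele_fraction(c(15, 0, 7), c(30, 25, 20)),
               c(0.5, 0, 0.35))
})

test_that("autosomal de novo gates pass and fail as specified", {
  clean <- make_record()  # child 15/30, parents 0/30, MQ 60
  res <- passes_denovo_filters(clean)
  expect_true(res$pass)
  expect_true(all(res$trace$pass))

  cases <- list(
    father_carries = make_record(ad_father = 3L),   # father AF 0.10
    low_child_dp = make_record(dp_child = 18L, ad_child = 9L),
    low_alt_depth = make_record(dp_child = 20L, ad_child = 4L,
                                ad_mother = 0L),
    low_mq = make_record(mq_father = 25),
    af_below_window = make_record(ad_child = 8L),   # AF 0.267
    af_above_window = make_record(ad_child = 22L),  # AF 0.733
    unevaluable = make_record(ad_mother = NA_integer_)
  )
  failed_rule <- c("father_absent", "depth_child", "alt_depth_child", "mq",
                   "child_af", "child_af", "evaluable")
  for (i in seq_along(cases)) {
    res <- passes_denovo_filters(cases[[i]])
    expect_false(res$pass, label = names(cases)[i])
    expect_false(res$trace$pass[res$trace$rule == failed_rule[i]],
                 label = paste(names(cases)[i], failed_rule[i]))
  }

  # window endpoints are inclusive
  expect_true(passes_denovo_filters(make_record(dp_child = 30L,
                                                ad_child = 9L))$pass)  # 0.30
  expect_true(passes_denovo_filters(make_record(dp_child = 30L,
                                                ad_child = 21L))$pass) # 0.70
})

test_that("X-chromosome rules depend on child sex", {
  # male child, hemizygous near-1 AF, father carries the allele: passes
  male_x <- make_record(chrom = "chrX", child_sex = "male",
                        dp_child = 40L, ad_child = 38L,
                        ad_father = 20L, dp_father = 40L)
  expect_true(passes_denovo_filters(male_x)$pass)

  # but the mother must be absent and covered
  expect_false(passes_denovo_filters(
    make_record(chrom = "chrX", child_sex = "male", dp_child = 40L,
                ad_child = 38L, ad_mother = 5L))$pass)
  expect_false(passes_denovo_filters(
    make_record(chrom = "chrX", child_sex = "male", dp_child = 40L,
                ad_child = 38L, dp_mother = 15L))$pass)

  # female child on X follows autosomal rules: father presence rejects,
  # and a near-homozygous AF fails the window
  expect_false(passes_denovo_filters(
    make_record(chrom = "chrX", child_sex = "female", ad_father = 20L,
                dp_father = 40L))$pass)
  expect_false(passes_denovo_filters(
    make_record(chrom = "chrX", child_sex = "female", dp_child = 40L,
                ad_child = 38L))$pass)
})

test_that("damage classification follows PTV / MPC rules", {
  expect_equal(classify_damage("stopgain"), "PTV")
  expect_equal(classify_damage(c("frameshift_insertion",
                                 "frameshift_deletion",
                                 "canonical_splice")),
               rep("PTV", 3))
  expect_equal(classify_damage("missense", 2.1), "MisD")
  expect_equal(classify_damage("missense", 2.0), "missense_other")  # strict
  expect_equal(classify_damage("missense", NA_real_), "missense_other")
  expect_equal(classify_damage("synonymous"), "synonymous")
  expect_equal(classify_damage("other"), "other")
  # classes partition the calls
  cons <- c("stopgain", "missense", "missense", "synonymous", "other")
  cls <- classify_damage(cons, c(NA, 3, 1, NA, NA))
  expect_true(all(cls %in% c("PTV", "MisD", "missense_other",
                             "synonymous", "other")))
})

test_that("rarity tiers use strict thresholds", {
  expect_equal(classify_rarity(3.36e-5), "ultra_rare")
  expect_equal(classify_rarity(0), "ultra_rare")
  expect_equal(classify_rarity(0.0005), "rare")
  expect_equal(classify_rarity(5e-5), "rare")      # boundary: not ultra-rare
  expect_equal(classify_rarity(0.001), "common")   # boundary: not rare
  expect_equal(classify_rarity(0.01), "common")
})

test_that("per-gene deduplication keeps the most severe call", {
  calls <- rbind(
    cbind(make_record(pos = 100L, consequence = "synonymous"),
          damage_class = "synonymous"),
    cbind(make_record(pos = 200L, consequence = "stopgain"),
          damage_class = "PTV"))
  kept <- dedupe_per_gene(calls)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$damage_class, "PTV")

  # calls in two different genes are both retained
  two_genes <- rbind(
    cbind(make_record(gene = "G1"), damage_class = "PTV"),
    cbind(make_record(gene = "G2", pos = 999L), damage_class = "PTV"))
  expect_equal(nrow(dedupe_per_gene(two_genes)), 2)

  # equal severity: lower position wins, then lexicographic alt allele
  tie <- rbind(
    cbind(make_record(pos = 300L, consequence = "missense", mpc = 3),
          damage_class = "MisD"),
    cbind(make_record(pos = 100L, consequence = "missense", mpc = 2.5),
          damage_class = "MisD"))
  expect_equal(dedupe_per_gene(tie)$pos, 100L)
  tie2 <- rbind(
    cbind(make_record(pos = 100L, alt = "T", consequence = "missense",
                      mpc = 3), damage_class = "MisD"),
    cbind(make_record(pos = 100L, alt = "C", consequence = "missense",
                      mpc = 2.5), damage_class = "MisD"))
  expect_equal(dedupe_per_gene(tie2)$alt_allele, "C")
})

test_that("trio QC excludes children with >20 de novo calls, strictly", {
  mk <- function(fam, n) {
    dplyr::bind_rows(lapply(seq_len(n), function(i)
      make_record(family_id = fam, gene = paste0("G", i),
                  pos = 1000L + i)))
  }
  calls <- dplyr::bind_rows(mk("over", 21), mk("at_limit", 20), mk("low", 3))
  qc <- trio_qc(calls)
  expect_equal(qc$excluded$family_id, "over")
  expect_equal(qc$excluded$n_calls, 21L)
  expect_setequal(qc$retained, c("at_limit", "low"))
  expect_setequal(unique(qc$calls$family_id), c("at_limit", "low"))
  # a family with zero calls is simply not excluded
  expect_false("empty_fam" %in% qc$excluded$family_id)
})

test_that("tightening any threshold never enlarges the call set", {
  cfg <- simulation_config(n_case_trios = 30, n_control_trios = 30,
                           gene_table = simulate_gene_table(80, seed = 5),
                           seed = 17)
  v <- simulate_trio_cohort(cfg)$variants
  base <- apply_denovo_filters(v, filter_thresholds())
  key <- function(x) paste(x$family_id, x$chrom, x$pos, x$alt_allele)
  passed_base <- key(base[base$pass, ])

  tighter <- list(
    filter_thresholds(min_depth = 30),
    filter_thresholds(child_af_min = 0.4, child_af_max = 0.6),
    filter_thresholds(parent_af_max = 0.01),
    filter_thresholds(min_alt_depth = 10),
    filter_thresholds(min_mq = 55)
  )
  for (th in tighter) {
    res <- apply_denovo_filters(v, th)
    expect_true(all(key(res[res$pass, ]) %in% passed_base))
  }
})

test_that("on simulated cohorts the caller recovers truth labels", {
  cfg <- simulation_config(n_case_trios = 80, n_control_trios = 80,
                           gene_table = simulate_gene_table(150, seed = 6),
                           seed = 23)
  coh <- simulate_trio_cohort(cfg)
  out <- call_denovos(coh$variants, keep_common = TRUE)
  calls <- out$calls

  truth_dn <- coh$variants[coh$variants$true_denovo, ]
  sens <- sum(calls$true_denovo) / nrow(truth_dn)
  spec_fp <- sum(!calls$true_denovo)

  # most true de novos survive the gates (Beta(20,20) AFs put a small tail
  # outside the window) and false calls are rare parental-noise events
  expect_gt(sens, 0.6)
  expect_lt(spec_fp / max(1, nrow(calls)), 0.1)
  # every emitted call is carried by the child
  expect_true(all(calls$ad_child > 0))
})
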