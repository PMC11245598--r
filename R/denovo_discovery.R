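# Trio-based de novo variant identification: per-variant evidence gates,
# rarity and damage classification, per-gene deduplication and trio-level QC.

#' De novo filter thresholds
#'
#' Bundles the stringent thresholds used to call a variant de novo in a
#' parent-child trio:
#' the child must be heterozygous with an alternate allele fraction inside
#' \[`child_af_min`, `child_af_max`\] (inclusive), each parent must be absent
#' for the allele (alternate allele fraction < `parent_af_max`), all three
#' members must have total depth >= `min_depth` at the site, the child's
#' alternate allele depth must be >= `min_alt_depth`, and mapping quality
#' must be >= `min_mq`. Rarity tiers use the gnomAD non-neuro allele
#' frequency: rare < `rare_af`, ultra-rare < `ultra_rare_af` (strict).
#' Children carrying more than `max_denovo_per_child` de novo calls are
#' excluded as outliers.
#'
#' On the X chromosome, male probands are hemizygous, so only the mother is
#' required to be absent (and covered), and the child allele-fraction window
#' widens to \[`child_af_min`, `male_x_af_max`\]; female probands are treated
#' as on autosomes.
#'
#' @param child_af_min,child_af_max Child alternate allele fraction window
#'   (inclusive at both ends).
#' @param parent_af_max Maximum parental alternate allele fraction (strict).
#' @param min_depth Minimum total depth in every required family member.
#' @param min_alt_depth Minimum alternate allele depth in the child.
#' @param min_mq Minimum mapping quality.
#' @param rare_af,ultra_rare_af Rarity thresholds on the gnomAD non-neuro
#'   allele frequency (strict `<`).
#' @param max_denovo_per_child Trio exclusion threshold (strict `>`).
#' @param male_x_af_max Upper child allele-fraction bound for hemizygous
#'   male-X calls.
#'
#' @return A list of thresholds with class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(child_af_min = 0.3, child_af_max = 0.7,
                              parent_af_max = 0.05, min_depth = 20,
                              min_alt_depth = 5, min_mq = 30,
                              rare_af = 0.001, ultra_rare_af = 0.00005,
                              max_denovo_per_child = 20,
                              male_x_af_max = 1.0) {
  stopifnot(child_af_min > 0, child_af_min < child_af_max, child_af_max < 1,
            parent_af_max > 0, min_depth >= 0, min_alt_depth >= 0,
            ultra_rare_af < rare_af, max_denovo_per_child > 0)
  structure(
    list(child_af_min = child_af_min, child_af_max = child_af_max,
         parent_af_max = parent_af_max, min_depth = min_depth,
         min_alt_depth = min_alt_depth, min_mq = min_mq,
         rare_af = rare_af, ultra_rare_af = ultra_rare_af,
         max_denovo_per_child = max_denovo_per_child,
         male_x_af_max = male_x_af_max),
    class = "filter_thresholds"
  )
}

#' Alternate allele fraction
#'
#' @param alt_depth Alternate allele read depth.
#' @param total_depth Total read depth.
#' @return `alt_depth / total_depth`, or `NA` (unevaluable, treated as a
#'   filter failure) when `total_depth` is zero or missing.
#' @export
allele_fraction <- function(alt_depth, total_depth) {
  out <- ifelse(!is.na(total_depth) & total_depth > 0 & !is.na(alt_depth),
                alt_depth / total_depth, NA_real_)
  as.numeric(out)
}

is_x_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) == "X"
}

filter_rule_names <- function() {
  c("evaluable", "child_af", "mother_absent", "father_absent",
    "depth_child", "depth_mother", "depth_father", "alt_depth_child", "mq")
}

#' Apply de novo evidence filters to a table of variant records
#'
#' Vectorized evaluation of every per-variant de novo rule. Autosomal
#' records pass when the child allele fraction lies in the configured window
#' (inclusive), both parents have allele fraction strictly below
#' `parent_af_max`, all three members meet the depth floor, the child meets
#' the alternate-depth floor, and mapping quality meets the floor. For
#' X-chromosome records with a male child, only the mother-absence and
#' mother-depth rules apply (the father's genotype cannot reject a
#' hemizygous call) and the child allele-fraction window is widened; female
#' children follow the autosomal rules. Records flagged unevaluable fail
#' the `evaluable` rule.
#'
#' @param variants Variant record tibble (see [read_trio_variants()]).
#' @param thresholds A [filter_thresholds()] object.
#' @return `variants` with one logical column per rule (prefixed `rule_`)
#'   and a logical `pass` column.
#' @export
apply_denovo_filters <- function(variants, thresholds = filter_thresholds()) {
  th <- thresholds
  v <- variants
  male_x <- is_x_chrom(v$chrom) & v$child_sex == "male"

  af_child <- allele_fraction(v$ad_child, v$dp_child)
  af_mother <- allele_fraction(v$ad_mother, v$dp_mother)
  af_father <- allele_fraction(v$ad_father, v$dp_father)
  mq <- pmin(v$mq_child, v$mq_mother, v$mq_father, na.rm = FALSE)

  evaluable <- if ("evaluable" %in% names(v)) v$evaluable else
    rep(TRUE, nrow(v))
  evaluable <- evaluable &
    !is.na(v$dp_child) & !is.na(v$ad_child) &
    !is.na(v$dp_mother) & !is.na(v$ad_mother) &
    (male_x | (!is.na(v$dp_father) & !is.na(v$ad_father)))

  af_hi <- ifelse(male_x, th$male_x_af_max, th$child_af_max)
  rule_child_af <- !is.na(af_child) &
    af_child >= th$child_af_min & af_child <= af_hi
  rule_mother_absent <- !is.na(af_mother) & af_mother < th$parent_af_max
  rule_father_absent <- male_x |
    (!is.na(af_father) & af_father < th$parent_af_max)
  rule_depth_child <- !is.na(v$dp_child) & v$dp_child >= th$min_depth
  rule_depth_mother <- !is.na(v$dp_mother) & v$dp_mother >= th$min_depth
  rule_depth_father <- male_x |
    (!is.na(v$dp_father) & v$dp_father >= th$min_depth)
  rule_alt_depth <- !is.na(v$ad_child) & v$ad_child >= th$min_alt_depth
  rule_mq <- !is.na(mq) & mq >= th$min_mq
  # male-X: father's MQ not required
  mq_mx <- pmin(v$mq_child, v$mq_mother)
  rule_mq[male_x] <- !is.na(mq_mx[male_x]) & mq_mx[male_x] >= th$min_mq

  out <- v
  out$rule_evaluable <- evaluable
  out$rule_child_af <- evaluable & rule_child_af
  out$rule_mother_absent <- evaluable & rule_mother_absent
  out$rule_father_absent <- evaluable & rule_father_absent
  out$rule_depth_child <- evaluable & rule_depth_child
  out$rule_depth_mother <- evaluable & rule_depth_mother
  out$rule_depth_father <- evaluable & rule_depth_father
  out$rule_alt_depth_child <- evaluable & rule_alt_depth
  out$rule_mq <- evaluable & rule_mq
  rule_cols <- grep("^rule_", names(out), value = TRUE)
  out$pass <- Reduce(`&`, out[rule_cols])
  out
}

#' Evaluate the de novo filters on a single variant record
#'
#' @param record A one-row variant record (tibble, data frame or named list).
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with `pass` (logical) and `trace`, a tibble of
#'   (rule, pass) pairs in evaluation order.
#' @export
passes_denovo_filters <- function(record, thresholds = filter_thresholds()) {
  rec <- tibble::as_tibble(as.list(record)[names(record) != ""])
  res <- apply_denovo_filters(rec, thresholds)
  rule_cols <- grep("^rule_", names(res), value = TRUE)
  trace <- tibble::tibble(
    rule = sub("^rule_", "", rule_cols),
    pass = vapply(rule_cols, function(cl) res[[cl]][1], TRUE)
  )
  list(pass = res$pass[1], trace = trace)
}

damage_levels <- function() {
  c("PTV", "MisD", "missense_other", "synonymous", "other")
}

#' Classify variant damage
#'
#' Protein-truncating variants (PTV) are stop-gains, frameshift
#' insertions/deletions and canonical splice-site variants. Missense
#' variants with MPC strictly greater than `mpc_threshold` are damaging
#' missense (MisD); other missense variants (including those with a missing
#' MPC score, which cannot satisfy the gate) are `missense_other`.
#' The "damaging" superset used in burden analysis is PTV plus MisD.
#'
#' @param consequence Character vector over the internal consequence
#'   vocabulary (see [normalize_consequence()]).
#' @param mpc Numeric MPC scores (`NA` allowed; only used for missense).
#' @param mpc_threshold Strict lower bound for MisD (default 2).
#' @return Character vector: `"PTV"`, `"MisD"`, `"missense_other"`,
#'   `"synonymous"` or `"other"`.
#' @export
classify_damage <- function(consequence, mpc = NA_real_, mpc_threshold = 2) {
  mpc <- rep_len(as.numeric(mpc), length(consequence))
  out <- rep("other", length(consequence))
  ptv <- consequence %in% c("stopgain", "frameshift_insertion",
                            "frameshift_deletion", "canonical_splice")
  out[ptv] <- "PTV"
  mis <- consequence == "missense"
  out[mis & !is.na(mpc) & mpc > mpc_threshold] <- "MisD"
  out[mis & (is.na(mpc) | mpc <= mpc_threshold)] <- "missense_other"
  out[consequence == "synonymous"] <- "synonymous"
  out
}

#' Classify population rarity
#'
#' Tiers a variant by its gnomAD non-neuro allele frequency: ultra-rare
#' (< `ultra_rare_af`), rare (< `rare_af`), otherwise common. Thresholds are
#' strict, and every ultra-rare variant is by construction also rare.
#'
#' @param gnomad_nonneuro_af Numeric allele frequencies in \[0, 1\].
#' @param thresholds A [filter_thresholds()] object.
#' @return Character vector: `"ultra_rare"`, `"rare"` or `"common"`.
#' @export
classify_rarity <- function(gnomad_nonneuro_af,
                            thresholds = filter_thresholds()) {
  af <- as.numeric(gnomad_nonneuro_af)
  stopifnot(all(is.na(af) | (af >= 0 & af <= 1)))
  out <- rep("common", length(af))
  out[!is.na(af) & af < thresholds$rare_af] <- "rare"
  out[!is.na(af) & af < thresholds$ultra_rare_af] <- "ultra_rare"
  out
}

#' Keep one variant per proband per gene
#'
#' When a child carries several calls in the same gene, only the most
#' severe is retained, with severity ordered
#' PTV > MisD > missense_other > synonymous > other. Ties are broken by
#' lower genomic position, then lexicographically by alternate allele.
#'
#' @param calls A call tibble with at least `family_id`, `gene`,
#'   `damage_class`, `pos` and `alt_allele` columns.
#' @return The deduplicated call tibble.
#' @export
dedupe_per_gene <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  sev <- match(calls$damage_class, damage_levels())
  ord <- order(calls$family_id, calls$gene, sev, calls$pos, calls$alt_allele)
  sorted <- calls[ord, ]
  keep <- !duplicated(sorted[, c("family_id", "gene")])
  sorted[keep, ]
}

#' Exclude trios with an outlier number of de novo calls
#'
#' Children observed with more than `max_denovo_per_child` de novo variants
#' (strictly greater) are removed from the cohort, a standard guard against
#' sample swaps and residual genotyping artifacts.
#'
#' @param calls A call tibble already past the per-variant filters.
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with `calls` (calls from retained families), `retained`
#'   (family IDs kept) and `excluded` (tibble of family_id and call count
#'   for dropped families).
#' @export
trio_qc <- function(calls, thresholds = filter_thresholds()) {
  counts <- table(calls$family_id)
  excl <- names(counts)[counts > thresholds$max_denovo_per_child]
  list(
    calls = calls[!(calls$family_id %in% excl), , drop = FALSE],
    retained = setdiff(names(counts), excl),
    excluded = tibble::tibble(family_id = excl,
                              n_calls = as.integer(counts[excl]))
  )
}

#' Full de novo calling pipeline on trio variant records
#'
#' Applies, in order: per-variant evidence gates, rarity classification
#' with removal of common variants, damage classification, one-variant-per-
#' proband-per-gene deduplication, and trio-level outlier exclusion.
#'
#' @param variants Variant record tibble (see [read_trio_variants()]).
#' @param thresholds A [filter_thresholds()] object.
#' @param keep_common Keep calls with gnomAD AF above the rare threshold
#'   (default `FALSE`, matching the rare-variant focus of trio studies).
#' @return A list with `calls` (the final call tibble, including `rarity`
#'   and `damage_class`), `excluded_families` and `n_input`.
#' @export
call_denovos <- function(variants, thresholds = filter_thresholds(),
                         keep_common = FALSE) {
  filtered <- apply_denovo_filters(variants, thresholds)
  calls <- filtered[filtered$pass, , drop = FALSE]
  calls$rarity <- classify_rarity(calls$gnomad_nonneuro_af, thresholds)
  if (!keep_common) {
    calls <- calls[calls$rarity != "common", , drop = FALSE]
  }
  calls$damage_class <- classify_damage(calls$consequence, calls$mpc)
  calls <- dedupe_per_gene(calls)
  qc <- trio_qc(calls, thresholds)
  list(calls = tibble::as_tibble(qc$calls),
       excluded_families = qc$excluded,
       n_input = nrow(variants))
}
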