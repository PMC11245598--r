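# Callable-exome mutation rates and exact Poisson comparisons between
# cases and controls.

#' Per-family callable base pairs
#'
#' Either validates a precomputed per-family coverage table, or computes
#' callable bp from per-site summaries: a locus is callable when its depth,
#' base quality and mapping quality all meet the thresholds used for de novo
#' calling AND it falls inside the capture-platform intersection.
#'
#' @param coverage Optional precomputed tibble with `family_id` and
#'   `callable_bp` (passed through after validation).
#' @param sites Optional per-site tibble with columns `family_id`, `chrom`,
#'   `pos` (1-based), `depth`, `base_quality`, `mapping_quality`.
#' @param capture_bed Optional tibble of capture intervals with columns
#'   `chrom`, `start`, `end` in standard BED semantics (0-based, half-open),
#'   e.g. from [read_bed()]. Required when `sites` is given.
#' @param families Optional character vector of family IDs that must all be
#'   present; a missing family is an error naming it.
#' @param min_depth,min_base_quality,min_mapping_quality Callability
#'   thresholds (defaults 20, 20, 30).
#' @return A tibble with `family_id` and `callable_bp`.
#' @export
callable_bp <- function(coverage = NULL, sites = NULL, capture_bed = NULL,
                        families = NULL, min_depth = 20,
                        min_base_quality = 20, min_mapping_quality = 30) {
  if (is.null(coverage) == is.null(sites)) {
    stop("supply exactly one of 'coverage' or 'sites'", call. = FALSE)
  }
  if (!is.null(sites)) {
    if (is.null(capture_bed)) {
      stop("'capture_bed' is required when computing from per-site summaries",
           call. = FALSE)
    }
    ok <- sites$depth >= min_depth &
      sites$base_quality >= min_base_quality &
      sites$mapping_quality >= min_mapping_quality &
      in_bed_intervals(sites$chrom, sites$pos, capture_bed)
    coverage <- tibble::as_tibble(
      stats::aggregate(list(callable_bp = ok),
                       by = list(family_id = sites$family_id), FUN = sum))
    coverage$callable_bp <- as.numeric(coverage$callable_bp)
  }
  if (any(coverage$callable_bp < 0)) {
    stop("negative callable_bp", call. = FALSE)
  }
  if (anyDuplicated(coverage$family_id)) {
    stop("duplicate family_id in coverage", call. = FALSE)
  }
  if (!is.null(families)) {
    miss <- setdiff(families, coverage$family_id)
    if (length(miss) > 0) {
      stop("no callable coverage for family: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  tibble::as_tibble(coverage)
}

#' Read a 3+ column BED file of capture intervals
#'
#' @param path Path to a BED file (0-based, half-open intervals).
#' @return A tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  if (any(bed$end <= bed$start)) {
    stop("BED intervals must satisfy start < end", call. = FALSE)
  }
  tibble::as_tibble(bed)
}

# 1-based position p is inside BED interval [start, end) iff start < p <= end
in_bed_intervals <- function(chrom, pos, bed) {
  out <- logical(length(pos))
  for (cm in unique(chrom)) {
    idx <- which(chrom == cm)
    iv <- bed[bed$chrom == cm, , drop = FALSE]
    if (nrow(iv) == 0) next
    out[idx] <- vapply(pos[idx], function(p) {
      any(p > iv$start & p <= iv$end)
    }, TRUE)
  }
  out
}

#' Haploid mutation rate with exact Poisson confidence interval
#'
#' The class-specific mutation count is divided by twice the summed callable
#' bp (each diploid genome contributes two callable haploid targets). The
#' confidence interval is the exact Poisson interval via the chi-square
#' relation: with `x` events the lower bound is
#' `qchisq(alpha/2, 2x)/2` (0 when `x = 0`) and the upper bound
#' `qchisq(1 - alpha/2, 2x + 2)/2`, each divided by `2T`.
#'
#' @param x Mutation count (nonnegative integer, vectorized).
#' @param total_bp Summed callable bp over families (positive).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `x`, `total_bp`, `rate`, `ci_low`, `ci_high`
#'   (all rates per haploid bp).
#' @export
haploid_rate <- function(x, total_bp, conf_level = 0.95) {
  if (any(total_bp <= 0)) stop("total callable bp must be positive",
                               call. = FALSE)
  if (any(x < 0)) stop("counts must be nonnegative", call. = FALSE)
  alpha <- 1 - conf_level
  denom <- 2 * total_bp
  lower <- ifelse(x == 0, 0, stats::qchisq(alpha / 2, 2 * x) / 2) / denom
  upper <- stats::qchisq(1 - alpha / 2, 2 * x + 2) / 2 / denom
  tibble::tibble(x = x, total_bp = total_bp, rate = x / denom,
                 ci_low = lower, ci_high = upper)
}

#' Exact one-tailed rate-ratio test between two Poisson rates
#'
#' Compares case and control haploid mutation rates with the exact
#' conditional test: given the total count `n = x_case + x_control`, under
#' the null of equal per-bp rates `x_case` is binomial with success
#' probability `t_case / (t_case + t_control)` (the haploid factor 2 cancels).
#' The one-tailed p-value for `alternative = "greater"` is the upper
#' binomial tail `P(X >= x_case)`; the rate-ratio confidence interval is
#' obtained by inverting the exact (Clopper-Pearson) interval for the
#' conditional proportion.
#'
#' @param x_case,x_control Mutation counts.
#' @param t_case,t_control Summed callable bp (exposure) per group.
#' @param alternative `"greater"` (default: case rate exceeds control),
#'   `"less"`, or `"two.sided"`.
#' @param conf_level Confidence level for the rate-ratio interval.
#' @return A tibble with `rate_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `alternative`, and the inputs. `x_case + x_control = 0` yields
#'   `p_value = 1` and an `NA` (flagged undefined) rate ratio.
#' @export
rate_ratio_test <- function(x_case, t_case, x_control, t_control,
                            alternative = c("greater", "less", "two.sided"),
                            conf_level = 0.95) {
  alternative <- match.arg(alternative)
  stopifnot(t_case > 0, t_control > 0, x_case >= 0, x_control >= 0)
  n <- x_case + x_control
  p0 <- t_case / (t_case + t_control)
  rr <- (x_case / (2 * t_case)) / (x_control / (2 * t_control))

  if (n == 0) {
    return(tibble::tibble(
      x_case = x_case, t_case = t_case, x_control = x_control,
      t_control = t_control, rate_ratio = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_value = 1, alternative = alternative))
  }

  bt <- stats::binom.test(x_case, n, p = p0,
                          alternative = alternative,
                          conf.level = conf_level)
  # transform the exact CI for the conditional proportion p into an RR CI:
  # RR = (p / (1 - p)) * (t_control / t_case)
  ci_p <- bt$conf.int
  odds <- function(p) ifelse(p >= 1, Inf, p / (1 - p))
  ci_rr <- odds(ci_p) * (t_control / t_case)

  tibble::tibble(
    x_case = x_case, t_case = t_case, x_control = x_control,
    t_control = t_control, rate_ratio = rr,
    ci_low = ci_rr[1], ci_high = ci_rr[2],
    p_value = bt$p.value, alternative = alternative
  )
}

burden_class_members <- function(class) {
  switch(class,
         all = damage_levels(),
         damaging = c("PTV", "MisD"),
         PTV = "PTV",
         MisD = "MisD",
         synonymous = "synonymous",
         stop("unknown variant class: ", class, call. = FALSE))
}

#' Case-versus-control de novo burden report
#'
#' For each requested variant class and rarity tier, counts de novo calls in
#' cases and controls, estimates per-group haploid mutation rates over the
#' summed callable exome with exact Poisson confidence intervals, and
#' compares the groups with the one-tailed exact rate-ratio test.
#'
#' A call contributes to a rarity tier if its tier is at least as rare as
#' requested (ultra-rare calls are also rare).
#'
#' @param case_calls,control_calls Call tibbles (see [call_denovos()]) with
#'   `damage_class` and `rarity` columns.
#' @param case_coverage,control_coverage Coverage tibbles (`family_id`,
#'   `callable_bp`).
#' @param classes Variant classes to report: any of `"all"`, `"damaging"`,
#'   `"PTV"`, `"MisD"`, `"synonymous"`.
#' @param rarities Rarity tiers to report: `"rare"` and/or `"ultra_rare"`.
#' @param alternative Direction of the rate-ratio test (default: case rate
#'   greater).
#' @param conf_level Confidence level for all intervals.
#' @return A list with `rates` (one row per class x rarity x group) and
#'   `ratios` (one row per class x rarity).
#' @export
burden_report <- function(case_calls, control_calls,
                          case_coverage, control_coverage,
                          classes = c("all", "damaging", "PTV", "MisD",
                                      "synonymous"),
                          rarities = c("rare", "ultra_rare"),
                          alternative = "greater", conf_level = 0.95) {
  if (is.null(case_calls) || is.null(case_coverage)) {
    stop("case calls and coverage are required", call. = FALSE)
  }
  if (is.null(control_calls) || is.null(control_coverage)) {
    stop("control calls and coverage are required", call. = FALSE)
  }
  t_case <- sum(case_coverage$callable_bp)
  t_control <- sum(control_coverage$callable_bp)

  count_calls <- function(calls, class, rarity) {
    keep <- calls$damage_class %in% burden_class_members(class)
    keep <- keep & switch(rarity,
                          rare = calls$rarity %in% c("rare", "ultra_rare"),
                          ultra_rare = calls$rarity == "ultra_rare",
                          stop("unknown rarity tier: ", rarity,
                               call. = FALSE))
    sum(keep)
  }

  rates <- list()
  ratios <- list()
  for (class in classes) {
    for (rarity in rarities) {
      x_ca <- count_calls(case_calls, class, rarity)
      x_co <- count_calls(control_calls, class, rarity)
      r_ca <- haploid_rate(x_ca, t_case, conf_level)
      r_co <- haploid_rate(x_co, t_control, conf_level)
      rates[[length(rates) + 1L]] <- tibble::tibble(
        variant_class = class, rarity = rarity,
        group = c("case", "control"),
        x = c(x_ca, x_co), total_bp = c(t_case, t_control),
        rate = c(r_ca$rate, r_co$rate),
        ci_low = c(r_ca$ci_low, r_co$ci_low),
        ci_high = c(r_ca$ci_high, r_co$ci_high))
      rt <- rate_ratio_test(x_ca, t_case, x_co, t_control,
                            alternative = alternative,
                            conf_level = conf_level)
      ratios[[length(ratios) + 1L]] <- tibble::tibble(
        variant_class = class, rarity = rarity,
        rate_ratio = rt$rate_ratio, ci_low = rt$ci_low,
        ci_high = rt$ci_high, p_value = rt$p_value)
    }
  }
  list(rates = dplyr::bind_rows(rates), ratios = dplyr::bind_rows(ratios))
}

#' Plot a burden report
#'
#' Mutation rates per class and group with Poisson confidence intervals,
#' faceted by rarity tier.
#'
#' @param report Output of [burden_report()].
#' @return A ggplot object.
#' @export
plot_burden <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_burden() requires the 'ggplot2' package", call. = FALSE)
  }
  ggplot2::ggplot(report$rates,
                  ggplot2::aes(x = .data$variant_class, y = .data$rate,
                               colour = .data$group)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~rarity) +
    ggplot2::labs(x = "variant class", y = "haploid mutation rate (per bp)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
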