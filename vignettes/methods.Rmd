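---
title: "Methods: de novo burden and Bayesian gene association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo burden and Bayesian gene association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovotada)
```

This vignette documents the statistical model behind `denovotada`, the
default parameter values and why they were chosen, the numerical decisions
made in the implementation, and the limitations of the synthetic cohort
simulator. Code blocks are illustrative; every quantitative claim made here
is recomputed either by the package's test suite or by
`scripts/acceptance.R`.

## 1. Scientific setting

The package analyzes *de novo* variants — variants present in a child but
in neither biological parent — discovered by whole-exome sequencing of
parent–child trios. The analysis has four stages:

1. **Discovery.** Candidate de novo calls are filtered from trio genotypes
   using allele-fraction, parental-absence, depth, and mapping-quality
   gates, then classified by predicted damage and population rarity.
2. **Burden.** Per-cohort haploid mutation rates are estimated against a
   callable-exome denominator and compared between cases and controls with
   an exact conditional test.
3. **Gene association.** Per-gene de novo counts (and optional independent
   case–control counts) are combined into TADA-style Bayes factors,
   posterior probabilities of risk-gene status, and Bayesian FDR q-values.
4. **Enrichment.** Ranked or thresholded gene lists are tested for
   over-representation in reference gene sets by the hypergeometric tail.

## 2. De novo discovery

### Filter gates

A candidate call in an autosomal gene passes when all of the following
hold (defaults from `filter_thresholds()`):

* child allele fraction AF = alt depth / total depth in **[0.3, 0.7]**,
  endpoints *inclusive*;
* each parent individually has AF **< 0.05** (strict) — a variant present
  in either parent is inherited, so the gate is per parent, not joint;
* total depth DP **≥ 20** in child, mother, and father;
* child alternate-allele depth **≥ 5** (parents are required absent, so a
  parental alt-depth floor would be meaningless);
* mapping quality **≥ 30**, applied site-level when per-sample MQ is
  unavailable.

On the X chromosome the rules depend on the child's sex. A male child is
hemizygous, so calls present near-homozygous: the AF window is widened to
**[0.3, 1.0]** and only the *mother's* absence and depth are required. A
female child follows the autosomal rules. The male-X widening is an
explicit design decision (the endpoint semantics of an AF "between"
window are genuinely ambiguous in the field; this package states them
once — inclusive — and tests the boundaries).

Records lacking the evidence needed to evaluate the gates (missing AD or
DP) are marked non-`evaluable` and never pass silently.

### Classification

* **PTV** (protein-truncating): stop-gain, frameshift insertion/deletion,
  or canonical splice-site variant.
* **MisD**: missense with MPC score **> 2** (strict).
* **damaging** = PTV ∪ MisD; synonymous variants serve as the negative
  control class.
* **rare**: gnomAD non-neuro allele frequency **< 1e-3**;
  **ultra-rare**: **< 5e-5** (both strict).

### Post-filters

* One variant per person per gene: within a (family, gene) pair the single
  most severe call is kept, severity ordered PTV > MisD > other missense >
  synonymous > other; ties break by lower position, then lexicographic
  alternate allele — a deterministic rule so that reruns are identical.
* Trio QC: a child with **more than 20** de novo calls is treated as a
  likely sample-quality artifact and the whole trio is excluded (strict
  `>`).

The filter order is fixed — evidence → genotype gates → rarity → dedupe →
trio QC — and each record carries per-rule pass/fail columns so failures
are attributable.

## 3. Burden statistics

### Haploid rate

With `x` calls over a summed callable denominator `T` base pairs across
`n` trios, the haploid rate is

$$\hat r = \frac{x}{2T},$$

because each trio contributes two haploid genomes' worth of opportunity.
The exact Poisson confidence interval uses the chi-square form: lower
bound `qchisq(alpha/2, 2x)/2 / (2T)` (0 when `x = 0`), upper
`qchisq(1 - alpha/2, 2x + 2)/2 / (2T)`. The test suite verifies this
closed form against direct inversion with `uniroot` and checks empirical
coverage lands in the nominal 94–96% band over 1000 simulations.

### Exact rate-ratio test

Conditional on the total count `n = x_case + x_control`, the case count is
binomial with success probability `T_case / (T_case + T_control)` under
the null of equal rates. `rate_ratio_test()` reports the one-tailed
binomial tail `P(X >= x_case)` and a rate-ratio confidence interval from
the Clopper–Pearson interval for the binomial proportion, mapped through
`RR = p/(1-p) * T_control/T_case`. Exactness is verified by brute-force
enumeration of the binomial tail for every `x <= n <= 50`, and validity
(`P(p <= alpha) <= alpha` under the null) follows and is asserted.
`callable_bp()` computes the denominator from per-site coverage or
per-family summaries, optionally intersected with capture BED intervals
(1-based positions against half-open `[start, end)` BED records).

## 4. TADA-style gene association

### Model

For gene *g* and variant category *c* (PTV or MisD), de novo counts are
Poisson with rate `2 N mu` under the null (`mu` = per-gene haploid
mutation rate, `N` = trios) and `2 N mu gamma` under the risk-gene
alternative, with relative risk `gamma ~ Gamma(gamma_mean * beta, beta)`.
Marginalizing gives a closed-form negative-binomial/Poisson Bayes factor:

$$BF_{dn} = \frac{\mathrm{NB}\!\left(x;\; \bar\gamma\beta,\;
\frac{\beta}{\beta + 2N\mu}\right)}{\mathrm{Pois}(x;\, 2N\mu)}.$$

The implementation is checked against adaptive quadrature of the integral
to 1e-8 relative error over a grid of counts and mutation rates (the
observed worst case is far below that; see `scripts/acceptance.R`).

For independent case–control counts the package conditions on the total
`n = x_case + x_control`, under which `x_case` is binomial with odds
proportional to `N_case * gamma : N_control`; the alternative marginalizes
over the Gamma prior by numerical integration.

Per-gene evidence multiplies across categories (BF of a missing category
is 1), the posterior probability of association is
`PP = pi * BF / (pi * BF + 1 - pi)`, and the Bayesian FDR q-value of a
gene is the running mean of `(1 - PP)` down the decreasing-PP ranking,
with tied PPs sharing the q of the last tied rank. Genes are tiered at
`q < 0.1` (high confidence) and `q < 0.3` (potential).

### Default hyperparameters

`tada_hyperparameters()` defaults to `pi = 0.055` and
(`gamma_mean`, `beta`) of (21.35, 0.82) for de novo PTV, (20.34, 0.83)
for de novo MisD, (1.78, 3.98) for case–control PTV, and (1.61, 6.17) for
case–control MisD. These are published ADHD extTADA posterior-mode
estimates and serve as the package's study conditions; they are defaults,
not tuned values, and every user-facing function accepts alternatives.
`risk_gene_count(pi, n_genes)` is the rounded extrapolation
`round(pi * n_genes)`; note that `risk_gene_count(0.055, 19560) = 1076`,
while an unrounded proportion printed as 5.50% can yield a slightly
different published count — rounding provenance matters and is
documented rather than hidden.

### Calibration

The test suite and acceptance script draw full cohorts from this
generative model (risk-gene indicators Bernoulli(`pi`), gammas from the
category priors, Poisson de novo counts, conditional-binomial
case–control counts) and verify that the realized false-discovery
proportion among `q < 0.1` selections stays at or below 0.15, and that
true risk genes rank above non-risk genes in every replicate.

## 5. Enrichment

`fisher_enrichment()` computes, for a query of size `s` drawn from a
universe of `U` genes and a reference set with `m` universe members and
`k` observed overlaps, the one-tailed hypergeometric tail
`phyper(k - 1, m, U - m, s, lower.tail = FALSE)`. Reference sets with
fewer than `min_overlap = 2` query overlaps are excluded *before* counting
the number of tests `N`; the rank-based correction is `q = p * N / r`
(reported raw as `q_raw` and capped at 1 as `q`), with significance called
at `p < 0.01` by default. For small universes the test suite checks `p`
against exhaustive enumeration of all `choose(U, s)` possible queries.
`build_gene_universe()` optionally removes the 58-symbol ACMG
secondary-findings list before association or enrichment, mirroring
common practice of excluding genes with ascertainment-biased reporting.

## 6. The synthetic cohort simulator

`simulate_trio_cohort()` exists so that every pipeline stage can be
exercised and validated without protected genotype data. What it emulates:

* per-trio de novo event counts Poisson with mean `2 * sum(mu)` over the
  gene table, events assigned to genes proportional to `mu`, with risk
  genes up-weighted by the class relative risk in **case** trios only
  (defaults: 5.5% risk genes, relative risks 21.35 PTV / 20.34 MisD);
* inherited background variants (mean `inherited_rate = 5` per trio) that
  should be removed by the parental-absence gate;
* heterozygous allele fractions Beta(20, 20); male-X hemizygous calls
  Beta(40, 2); parental sequencing error at AF 0.005;
* negative-binomial depths (mean 60, size 10), Gaussian MQ (mean 60,
  sd 3), Gaussian per-family callable denominators (mean 3e7, sd 2e6);
* a 12.5% chance that a true de novo is coincidentally present in gnomAD
  at AF in [1e-5, 5e-5], so the ultra-rare gate is exercised on both
  sides;
* cohort sizes default to 147 case and 780 control trios, the scale of a
  typical single-study trio cohort.

Every simulated variant carries its truth label, so call sets can be
scored for sensitivity and false-positive content. Cohorts can be
round-tripped to disk (`write_cohort_vcf()`, `write_pedigree()`,
`write_coverage_table()`) and re-read through the same readers used for
real data.

What the simulator does **not** emulate: mosaicism, multi-nucleotide
events, strand or batch artifacts, relatedness or ancestry structure,
capture-platform coverage heterogeneity within a family, and genotype
caller idiosyncrasies. It is a model of the *statistical* pipeline, not of
a sequencer.

These defaults are the package's study conditions: they were fixed before
the validation experiments were run, and the tests are written against
them rather than the other way around.

## 7. Numerical decisions

* **Quadrature bounds.** `case_control_bf()` integrates over the Gamma
  prior's quantile range `qgamma(c(1e-14, 1 - 1e-14), ...)` rather than
  `(0, Inf)`: for sharply concentrated priors, adaptive quadrature on an
  infinite interval can miss the mass spike entirely and silently return
  0. The truncation discards at most 2e-14 of prior mass.
* **Mutation-rate floor.** `denovo_bf()` replaces `mu = 0` with
  `mu_floor = 1e-9` so a zero annotated rate with a nonzero observed
  count yields strong but finite evidence instead of a 0/0.
* **Inclusive AF window, strict `<` thresholds.** Stated once in
  `filter_thresholds()` documentation and tested exactly at the
  boundaries (AF 9/30 and 21/30 pass; MPC exactly 2 is *not* MisD;
  AF exactly 5e-5 is rare-but-not-ultra-rare; exactly 1e-3 is common).
* **Deterministic tie-breaks** in `dedupe_per_gene()` (position, then
  alternate allele) so results are invariant to input row order.
* **Multi-allelic sites** are decomposed into one record per alternate
  allele *before* filtering, so each allele is gated on its own depths.
* **Seeding.** All simulator entry points take explicit seeds and restore
  the caller's RNG state on exit (`with_seed()`), so library code never
  perturbs a user's random stream.

## 8. Problem sizes used in validation

The validation experiments run at sizes chosen for statistical
resolution within desk-scale runtimes: 1000 simulations for interval
coverage; 500 null cohorts of 100 + 100 trios for p-value uniformity
(exact conditional tests are discrete, so uniformity is assessed on a
coarse grid of levels with a conservative Kolmogorov–Smirnov bound);
20 replicates of 5000 genes with 1000 trios and 3206/5002 case–control
samples for FDR calibration; exhaustive enumeration limited to universes
of at most 25 genes. These sizes are the package's own choices.

## 9. Limitations

* The discovery stage scores genotype evidence already present in an
  annotated VCF; it does not realign reads or model mosaicism.
* Hyperparameter *estimation* (the MCMC that produces `pi`, `gamma_mean`,
  `beta` from data) is out of scope; the package consumes published or
  user-supplied values.
* The case–control Bayes factor assumes the external counts are
  independent of the trio data and share the gene's risk status.
* Published cohort-level burden statistics can only be recomputed when
  the per-family call and coverage tables are available; the package
  ships the machinery and a fixture-based end-to-end test, not the
  protected data.
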