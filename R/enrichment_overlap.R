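# Gene-list overlap with reference risk-gene sets and Fisher/hypergeometric
# over-representation analysis with rank-based q-values.

#' Overlap a query gene list with reference gene sets
#'
#' @param query Character vector of gene symbols.
#' @param reference_sets A [gene_set_collection()].
#' @return A tibble with one row per set: `set`, `set_size`, `overlap_count`
#'   and `overlap_genes` (comma-separated). Sets with zero overlap are
#'   retained with count 0.
#' @export
overlap_gene_sets <- function(query, reference_sets) {
  if (length(query) == 0) stop("query gene list is empty", call. = FALSE)
  query <- unique(toupper(query))
  rows <- lapply(names(reference_sets), function(nm) {
    hits <- sort(intersect(query, reference_sets[[nm]]))
    tibble::tibble(set = nm, set_size = length(reference_sets[[nm]]),
                   overlap_count = length(hits),
                   overlap_genes = paste(hits, collapse = ","))
  })
  dplyr::bind_rows(rows)
}

#' Over-representation analysis with the exact hypergeometric test
#'
#' For each reference set, tests whether the query list overlaps the set
#' more than expected when drawing `|query|` genes at random from the
#' universe: the one-tailed p-value is the upper hypergeometric tail
#' `P(K >= k)`. Sets whose overlap is below `min_overlap` are excluded
#' before testing (and do not count towards the number of tests `N`).
#' Multiple testing uses the rank-based correction `q = p * N / r`, where
#' `r` is the rank of the p-value among the `N` tested sets; the raw value
#' is retained in `q_raw` and capped at 1 in `q`.
#'
#' @param query Character vector of gene symbols (must be within `universe`).
#' @param reference_sets A [gene_set_collection()].
#' @param universe Character vector: the gene universe (e.g. the association
#'   universe after ACMG exclusion).
#' @param min_overlap Minimum overlap for a set to be tested (default 2).
#' @param p_cutoff Only results with `p < p_cutoff` are flagged
#'   `significant` (default 0.01); all tested sets are returned.
#' @return A tibble with one row per tested set: overlap statistics, `p`,
#'   rank `r`, `n_tests`, `q_raw`, `q` and `significant`, sorted by `p`.
#' @export
fisher_enrichment <- function(query, reference_sets, universe,
                              min_overlap = 2, p_cutoff = 0.01) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  if (length(universe) < length(query)) {
    stop("universe is smaller than the query list", call. = FALSE)
  }
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  s <- length(query)
  u <- length(universe)

  rows <- lapply(names(reference_sets), function(nm) {
    members <- intersect(reference_sets[[nm]], universe)
    hits <- sort(intersect(query, members))
    tibble::tibble(set = nm, set_size = length(members),
                   overlap_count = length(hits),
                   overlap_genes = paste(hits, collapse = ","))
  })
  tab <- dplyr::bind_rows(rows)
  tab <- tab[tab$overlap_count >= min_overlap, , drop = FALSE]
  if (nrow(tab) == 0) {
    return(tibble::tibble(set = character(), set_size = integer(),
                          overlap_count = integer(),
                          overlap_genes = character(), p = numeric(),
                          r = integer(), n_tests = integer(),
                          q_raw = numeric(), q = numeric(),
                          significant = logical()))
  }
  # upper tail P(K >= k) for K ~ Hypergeometric(m, u - m, s)
  tab$p <- stats::phyper(tab$overlap_count - 1, tab$set_size,
                         u - tab$set_size, s, lower.tail = FALSE)
  n_tests <- nrow(tab)
  tab <- tab[order(tab$p, tab$set), ]
  tab$r <- rank(tab$p, ties.method = "max")
  tab$n_tests <- n_tests
  tab$q_raw <- tab$p * n_tests / tab$r
  tab$q <- pmin(tab$q_raw, 1)
  tab$significant <- tab$p < p_cutoff
  tab
}
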