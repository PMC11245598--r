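# Readers and writers for the external formats the pipeline touches:
# multi-sample trio VCF, 6-column PED, per-family coverage TSV, GMT gene
# sets, and the tab-separated de novo call table.

#' Annotation tag configuration for VCF INFO fields
#'
#' Variant annotations (gene symbol, consequence, MPC score, gnomAD
#' non-neuro allele frequency) are consumed from VCF INFO fields whose names
#' vary between annotation pipelines. The defaults follow common
#' ANNOVAR/RefSeq output; override any tag to match your VCF.
#'
#' @param gene INFO key holding the gene symbol.
#' @param consequence INFO key holding the functional consequence.
#' @param mpc INFO key holding the MPC score for missense variants.
#' @param gnomad_af INFO key holding the gnomAD non-neuro allele frequency.
#' @param mq INFO key holding the site-level mapping quality, used when
#'   per-sample mapping quality is unavailable.
#'
#' @return A named list of tag names with class `"annotation_tags"`.
#' @export
annotation_tags <- function(gene = "Gene.refGene",
                            consequence = "ExonicFunc.refGene",
                            mpc = "MPC",
                            gnomad_af = "gnomAD_nonneuro_AF",
                            mq = "MQ") {
  structure(
    list(gene = gene, consequence = consequence, mpc = mpc,
         gnomad_af = gnomad_af, mq = mq),
    class = "annotation_tags"
  )
}

#' Normalize a consequence annotation to the internal vocabulary
#'
#' Maps common annotation spellings (e.g. ANNOVAR's `nonsynonymous_SNV`,
#' `stopgain`, `frameshift_deletion`, `splicing`) onto the classes used by
#' the damage classifier: `stopgain`, `frameshift_insertion`,
#' `frameshift_deletion`, `canonical_splice`, `missense`, `synonymous`,
#' `other`.
#'
#' @param x Character vector of raw consequence strings.
#' @return Character vector over the internal consequence vocabulary.
#' @export
normalize_consequence <- function(x) {
  key <- gsub("[ -]", "_", tolower(trimws(as.character(x))))
  out <- rep("other", length(key))
  out[key %in% c("stopgain", "stop_gained", "nonsense")] <- "stopgain"
  out[key %in% c("frameshift_insertion", "frameshift_ins")] <- "frameshift_insertion"
  out[key %in% c("frameshift_deletion", "frameshift_del")] <- "frameshift_deletion"
  out[key %in% c("splicing", "canonical_splice", "splice_acceptor_variant",
                 "splice_donor_variant", "splice_site")] <- "canonical_splice"
  out[key %in% c("missense", "nonsynonymous_snv", "missense_variant")] <- "missense"
  out[key %in% c("synonymous", "synonymous_snv", "synonymous_variant")] <- "synonymous"
  out[is.na(x)] <- NA_character_
  out
}

consequence_levels <- function() {
  c("stopgain", "frameshift_insertion", "frameshift_deletion",
    "canonical_splice", "missense", "synonymous", "other")
}

#' Read a pedigree file
#'
#' Reads a standard 6-column PED file (family, individual, father, mother,
#' sex, phenotype) describing parent-child trios, and assigns each member a
#' trio role. Every family must contain exactly one child (an individual
#' whose father and mother IDs point at the other two members) plus that
#' mother and father.
#'
#' @param path Path to a whitespace-delimited PED file without header.
#' @return A tibble with columns `family_id`, `member_id`, `role`
#'   (`"child"`, `"mother"`, `"father"`), `sex` (`"male"`/`"female"`) and
#'   `affected` (logical).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "member_id",
                                         "father_id", "mother_id",
                                         "sex", "phenotype"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "integer"))
  out <- lapply(split(ped, ped$family_id), function(fam) {
    is_child <- fam$father_id != "0" & fam$mother_id != "0"
    if (sum(is_child) != 1L) {
      stop("family '", fam$family_id[1],
           "' must contain exactly one child with both parents; found ",
           sum(is_child), call. = FALSE)
    }
    child <- fam[is_child, ]
    role <- rep(NA_character_, nrow(fam))
    role[is_child] <- "child"
    role[fam$member_id == child$father_id] <- "father"
    role[fam$member_id == child$mother_id] <- "mother"
    if (anyNA(role) || !setequal(role, c("child", "mother", "father"))) {
      stop("family '", fam$family_id[1],
           "' does not form a complete trio (child, mother, father)",
           call. = FALSE)
    }
    tibble::tibble(
      family_id = fam$family_id,
      member_id = fam$member_id,
      role = role,
      sex = c("male", "female", NA_character_)[match(fam$sex, c(1L, 2L, 0L))],
      affected = fam$phenotype == 2L
    )
  })
  dplyr::bind_rows(out)
}

info_field <- function(info, key) {
  pattern <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pattern, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

format_field <- function(gt, format, key) {
  keys <- strsplit(format, ":", fixed = TRUE)
  vals <- strsplit(gt, ":", fixed = TRUE)
  mapply(function(k, v) {
    i <- match(key, k)
    if (is.na(i) || i > length(v)) NA_character_ else v[i]
  }, keys, vals, USE.NAMES = FALSE)
}

#' Read trio variant records from a jointly called VCF
#'
#' Extracts one record per (family, site, alternate allele) from a
#' multi-sample VCF, attaching per-member depth (DP), alternate-allele depth
#' (AD) and mapping-quality evidence for the child, mother and father of
#' every trio in `pedigree`. Multi-allelic sites are decomposed into one
#' record per alternate allele. Records missing a required per-member depth
#' field are retained with `evaluable = FALSE` rather than dropped, so
#' downstream filtering can report them.
#'
#' Only sites at which the child carries at least one copy of the alternate
#' allele (per genotype or a nonzero alternate depth) produce a record for
#' that family.
#'
#' @param vcf_path Path to a VCF 4.x file with per-sample DP and AD.
#' @param pedigree Pedigree tibble from [read_pedigree()].
#' @param tags Annotation tag configuration from [annotation_tags()].
#' @param chr_style `"asis"` (default), `"strip"` or `"add"`: whether to
#'   leave chromosome labels unchanged, strip a `"chr"` prefix, or add one.
#' @return A tibble of variant records with columns `family_id`, `chrom`,
#'   `pos` (1-based), `ref_allele`, `alt_allele`, `gene`, `consequence`,
#'   `mpc`, `gnomad_nonneuro_af`, `child_sex`, per-member `dp_*`, `ad_*`,
#'   `mq_*` and `evaluable`.
#' @export
read_trio_variants <- function(vcf_path, pedigree, tags = annotation_tags(),
                               chr_style = c("asis", "strip", "add")) {
  chr_style <- match.arg(chr_style)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  samples <- colnames(gt)[-1]

  missing <- setdiff(pedigree$member_id, samples)
  if (length(missing) > 0) {
    stop("pedigree member(s) absent from VCF: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  chrom <- fix$CHROM
  if (chr_style == "strip") chrom <- sub("^chr", "", chrom)
  if (chr_style == "add") chrom <- ifelse(grepl("^chr", chrom), chrom,
                                          paste0("chr", chrom))

  info <- fix$INFO
  gene <- info_field(info, tags$gene)
  consequence <- normalize_consequence(info_field(info, tags$consequence))
  mpc <- suppressWarnings(as.numeric(info_field(info, tags$mpc)))
  af <- suppressWarnings(as.numeric(info_field(info, tags$gnomad_af)))
  mq_site <- suppressWarnings(as.numeric(info_field(info, tags$mq)))
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("malformed allele frequency outside [0, 1] in INFO field '",
         tags$gnomad_af, "'", call. = FALSE)
  }

  fams <- split(pedigree, pedigree$family_id)
  rows <- vector("list", length(fams))
  format_col <- gt[, 1]

  for (fi in seq_along(fams)) {
    fam <- fams[[fi]]
    ids <- stats::setNames(fam$member_id, fam$role)
    child_sex <- fam$sex[fam$role == "child"]

    member_evidence <- lapply(c(child = "child", mother = "mother",
                                father = "father"), function(role) {
      col <- gt[, ids[[role]]]
      list(
        gt = format_field(col, format_col, "GT"),
        dp = suppressWarnings(as.integer(format_field(col, format_col, "DP"))),
        ad = format_field(col, format_col, "AD"),
        mq = suppressWarnings(as.numeric(format_field(col, format_col, "MQ")))
      )
    })

    alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
    site_rows <- vector("list", nrow(fix))
    for (si in seq_len(nrow(fix))) {
      alts <- alt_list[[si]]
      for (ai in seq_along(alts)) {
        ev <- lapply(member_evidence, function(m) {
          ad_vec <- suppressWarnings(
            as.integer(strsplit(m$ad[si], ",", fixed = TRUE)[[1]]))
          alt_ad <- if (length(ad_vec) >= ai + 1L) ad_vec[ai + 1L] else NA_integer_
          list(gt = m$gt[si], dp = m$dp[si], ad = alt_ad,
               mq = if (is.na(m$mq[si])) mq_site[si] else m$mq[si])
        })
        child_gt <- ev$child$gt
        carries <- (!is.na(child_gt) &&
                      ai %in% suppressWarnings(
                        as.integer(strsplit(child_gt, "[/|]")[[1]]))) ||
          (!is.na(ev$child$ad) && ev$child$ad > 0)
        if (!isTRUE(carries)) next
        evaluable <- !anyNA(c(ev$child$dp, ev$child$ad,
                              ev$mother$dp, ev$mother$ad,
                              ev$father$dp, ev$father$ad))
        site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
          family_id = fam$family_id[1],
          chrom = chrom[si],
          pos = as.integer(fix$POS[si]),
          ref_allele = fix$REF[si],
          alt_allele = alts[ai],
          gene = gene[si],
          consequence = consequence[si],
          mpc = mpc[si],
          gnomad_nonneuro_af = af[si],
          child_sex = child_sex,
          dp_child = ev$child$dp, ad_child = ev$child$ad, mq_child = ev$child$mq,
          dp_mother = ev$mother$dp, ad_mother = ev$mother$ad, mq_mother = ev$mother$mq,
          dp_father = ev$father$dp, ad_father = ev$father$ad, mq_father = ev$father$mq,
          evaluable = evaluable
        )
      }
    }
    rows[[fi]] <- dplyr::bind_rows(site_rows[!vapply(site_rows, is.null, TRUE)])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(empty_variant_records())
  }
  bad_ad <- !is.na(out$ad_child) & !is.na(out$dp_child) &
    out$ad_child > out$dp_child
  if (any(bad_ad)) {
    stop("alternate allele depth exceeds total depth for ",
         sum(bad_ad), " child record(s)", call. = FALSE)
  }
  out
}

empty_variant_records <- function() {
  tibble::tibble(
    family_id = character(), chrom = character(), pos = integer(),
    ref_allele = character(), alt_allele = character(), gene = character(),
    consequence = character(), mpc = numeric(),
    gnomad_nonneuro_af = numeric(), child_sex = character(),
    dp_child = integer(), ad_child = integer(), mq_child = numeric(),
    dp_mother = integer(), ad_mother = integer(), mq_mother = numeric(),
    dp_father = integer(), ad_father = integer(), mq_father = numeric(),
    evaluable = logical()
  )
}

#' Read a per-family callable-coverage table
#'
#' Reads the tab-separated table giving, for every trio, the number of
#' callable base pairs: loci sequenced to sufficient depth and quality in
#' all three family members within the capture-platform intersection. This
#' is the denominator of the per-family mutation rate.
#'
#' @param path Path to a TSV with header columns `family_id` and
#'   `callable_bp`.
#' @return A tibble with one row per family.
#' @export
read_coverage_table <- function(path) {
  cov <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric"))
  if (!all(c("family_id", "callable_bp") %in% names(cov))) {
    stop("coverage table must have columns 'family_id' and 'callable_bp'",
         call. = FALSE)
  }
  if (nrow(cov) == 0) {
    warning("coverage table '", path, "' is empty", call. = FALSE)
    return(tibble::tibble(family_id = character(), callable_bp = numeric()))
  }
  if (anyDuplicated(cov$family_id)) {
    stop("duplicate family_id in coverage table: ",
         paste(unique(cov$family_id[duplicated(cov$family_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(cov$callable_bp < 0)) {
    stop("negative callable_bp in coverage table", call. = FALSE)
  }
  tibble::as_tibble(cov)
}

#' Read a GMT gene-set collection
#'
#' Parses the standard GMT format (one set per line: name, description, then
#' tab-separated gene symbols). Symbols are uppercased and deduplicated
#' within each set.
#'
#' @param path Path to a GMT file.
#' @return An object of class `"gene_set_collection"`: a named list of
#'   character vectors, with a `description` attribute mapping set names to
#'   their source labels.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields",
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(toupper(trimws(f[-c(1, 2)]))))
  names(sets) <- vapply(fields, `[`, "", 1L)
  desc <- stats::setNames(vapply(fields, `[`, "", 2L), names(sets))
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param description Optional named character vector of source labels.
#' @return An object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (any(vapply(sets, length, 0L) == 0L)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, description = description, class = "gene_set_collection")
}

#' @method print gene_set_collection
#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "set(s)\n")
  for (nm in utils::head(names(x), 10)) {
    cat("  ", nm, ": ", length(x[[nm]]), " genes\n", sep = "")
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

denovo_table_columns <- function() {
  c("family_id", "gene", "chrom", "pos", "ref_allele", "alt_allele",
    "consequence", "damage_class", "rarity", "mpc", "gnomad_nonneuro_af")
}

#' Write a de novo call table
#'
#' Writes calls as a TSV mirroring the usual published layout: proband ID,
#' gene, genomic coordinate, alleles, consequence, damage class, rarity
#' tier, MPC (missense only) and gnomAD non-neuro allele frequency. The
#' output round-trips losslessly through [read_denovo_table()].
#'
#' @param calls A tibble of de novo calls (as produced by [call_denovos()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_denovo_table <- function(calls, path) {
  cols <- denovo_table_columns()
  missing <- setdiff(cols, names(calls))
  if (length(missing) > 0) {
    stop("calls table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(calls[, cols])
  # full precision so AF/MPC survive the round trip
  for (col in c("mpc", "gnomad_nonneuro_af")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(out[[col]], digits = 17, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a de novo call table written by [write_denovo_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble of de novo calls.
#' @export
read_denovo_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = c(
                            family_id = "character", gene = "character",
                            chrom = "character", pos = "integer",
                            ref_allele = "character", alt_allele = "character",
                            consequence = "character",
                            damage_class = "character", rarity = "character",
                            mpc = "numeric", gnomad_nonneuro_af = "numeric"))
  tibble::as_tibble(df)
}
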