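# Bundled example dataset: the 24 ultra-rare de novo damaging variants
# observed in 23 of 147 ADHD probands in a published whole-exome
# parent-child trio study, as curated from its printed variant table.

#' Ultra-rare de novo damaging variants from an ADHD trio cohort
#'
#' A curated table of the 24 ultra-rare de novo damaging variants (PTV or
#' MisD) identified in 23 probands of a 147-trio ADHD whole-exome study.
#' One proband carries variants in two genes, and one gene (*KDM5B*)
#' carries de novo PTVs in two unrelated probands. The `ndd_risk_gene`
#' column flags the six genes also reported as likely risk genes
#' (FDR < 0.05) in a large autism / developmental-delay meta-analysis.
#'
#' Indel REF/ALT alleles are represented in left-anchored VCF style
#' (deletions carry the longer REF); coordinates are 1-based on hg19.
#'
#' @return A tibble with columns `proband_id`, `gene`, `protein_change`,
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `consequence` (raw
#'   annotation spelling), `mpc` (missense only), `pli` (as printed, e.g.
#'   `"<0.001"`), `gnomad_nonneuro_af`, `ndd_risk_gene`, `ndd_conditions`.
#' @export
adhd_denovo_calls <- function() {
  tibble::tribble(
    ~proband_id, ~gene, ~protein_change, ~chrom, ~pos, ~ref_allele,
    ~alt_allele, ~consequence, ~mpc, ~pli, ~gnomad_nonneuro_af,
    ~ndd_risk_gene, ~ndd_conditions,
    "ADHD6.p1",   "RBBP6",     "p.Y170C",  "chr16", 24567213L,  "A",     "G",   "missense",             2.1, "1",      0,       FALSE, NA,
    "ADHD14.p1",  "YLPM1",     "p.R1646X", "chr14", 75276497L,  "C",     "T",   "stopgain",             NA,  "<0.001", 0,       FALSE, NA,
    "ADHD25.p1",  "SECISBP2L", "p.T934fs", "chr15", 49284809L,  "TG",    "T",   "frameshift deletion",  NA,  "0.981",  0,       FALSE, NA,
    "ADHD33.p1",  "NARS2",     "p.R54X",   "chr11", 78282471L,  "G",     "A",   "stopgain",             NA,  "<0.001", 3.36e-5, FALSE, NA,
    "ADHD37.p1",  "CTNNA2",    "p.R348W",  "chr2",  80808942L,  "C",     "T",   "missense",             2.6, "0.975",  0,       TRUE,  "ASD",
    "ADHD44.p1",  "BEST4",     "p.L207fs", "chr1",  45251759L,  "CAGAG", "C",   "frameshift deletion",  NA,  "<0.001", 0,       FALSE, NA,
    "ADHD50.p1",  "KDM5B",     "p.R1093X", "chr1",  202704703L, "G",     "A",   "stopgain",             NA,  "<0.001", 1.12e-5, TRUE,  "ASD and DD",
    "ADHD57.p1",  "STAG1",     "p.R1088X", "chr3",  136068009L, "G",     "A",   "stopgain",             NA,  "1",      0,       TRUE,  "DD",
    "ADHD58.p1",  "KDM5B",     "p.D806fs", "chr1",  202711840L, "TC",    "T",   "frameshift deletion",  NA,  "<0.001", 0,       TRUE,  "ASD and DD",
    "ADHD61.p1",  "EML6",      "p.R313X",  "chr2",  55071273L,  "C",     "T",   "stopgain",             NA,  "<0.001", 0,       TRUE,  NA,
    "ADHD69.p1",  "CFL1",      "p.Y82C",   "chr11", 65623472L,  "T",     "C",   "missense",             3.2, "0.990",  0,       FALSE, NA,
    "ADHD71.p1",  "OCEL1",     "p.G34X",   "chr19", 17337532L,  "G",     "T",   "stopgain",             NA,  "<0.001", 0,       FALSE, NA,
    "ADHD71.p1",  "TTC26",     "p.G24D",   "chr7",  138819468L, "G",     "A",   "splicing",             NA,  "<0.001", 0,       FALSE, NA,
    "ADHD84.p1",  "PLD5",      "p.D28fs",  "chr1",  242511463L, "TG",    "T",   "frameshift deletion",  NA,  "<0.001", 0,       FALSE, NA,
    "ADHD86.p1",  "FBXO11",    "p.P918S",  "chr2",  48035289L,  "G",     "A",   "missense",             2.6, "1",      0,       TRUE,  "ASD and DD",
    "ADHD95.p1",  "CHST15",    "p.L214fs", "chr10", 125804342L, "G",     "GGT", "frameshift insertion", NA,  "<0.001", 0,       FALSE, NA,
    "ADHD98.p1",  "EHBP1L1",   "p.M1429fs","chr11", 65359271L,  "CATGG", "C",   "frameshift deletion",  NA,  "<0.001", 0,       FALSE, NA,
    "ADHD99.p1",  "TUBB",      "p.G233E",  "chr6",  30691669L,  "G",     "A",   "missense",             3.3, "1",      0,       FALSE, NA,
    "ADHD107.p1", "CTNND2",    "p.V229fs", "chr5",  11236867L,  "AC",    "A",   "frameshift deletion",  NA,  "1",      0,       FALSE, NA,
    "ADHD117.p1", "GOLGB1",    "p.Y288X",  "chr3",  121435768L, "A",     "C",   "stopgain",             NA,  "0.003",  0,       FALSE, NA,
    "ADHD130.p1", "L1TD1",     "p.S580X",  "chr1",  62676185L,  "C",     "A",   "stopgain",             NA,  "<0.001", 0,       FALSE, NA,
    "ADHD134.p1", "GNB2L1",    "p.N244D",  "chr5",  180665146L, "T",     "C",   "missense",             2.2, "1",      0,       FALSE, NA,
    "ADHD141.p1", "PAK1",      "c.C44T",   "chr11", 77103522L,  "G",     "A",   "missense",             2.8, "0.059",  0,       TRUE,  "DD",
    "ADHD144.p1", "USP54",     "p.R58X",   "chr10", 75331247L,  "G",     "A",   "stopgain",             NA,  "<0.001", 3.30e-5, FALSE, NA
  )
}

#' Example calls as trio variant records with synthetic evidence
#'
#' Converts [adhd_denovo_calls()] into the variant-record layout consumed by
#' the filtering pipeline. Per-member read evidence (depths, alternate
#' depths, mapping quality) is synthetic: the underlying reads are not
#' public, so each record is given nominal evidence consistent with a clean
#' heterozygous de novo call (child 15/30 reads, parents 0/30, MQ 60).
#'
#' @return A variant-record tibble (see [read_trio_variants()]).
#' @export
adhd_denovo_variant_records <- function() {
  calls <- adhd_denovo_calls()
  tibble::tibble(
    family_id = calls$proband_id,
    chrom = calls$chrom,
    pos = calls$pos,
    ref_allele = calls$ref_allele,
    alt_allele = calls$alt_allele,
    gene = calls$gene,
    consequence = normalize_consequence(calls$consequence),
    mpc = calls$mpc,
    gnomad_nonneuro_af = calls$gnomad_nonneuro_af,
    child_sex = "male",
    dp_child = 30L, ad_child = 15L, mq_child = 60,
    dp_mother = 30L, ad_mother = 0L, mq_mother = 60,
    dp_father = 30L, ad_father = 0L, mq_father = 60,
    evaluable = TRUE
  )
}
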