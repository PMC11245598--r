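# Shared fixture builders: a one-row variant record with clean de novo
# evidence, and a small handcrafted trio VCF + PED pair.

make_record <- function(chrom = "chr1", pos = 1000L, ref = "G", alt = "A",
                        gene = "GENE1", consequence = "stopgain",
                        mpc = NA_real_, af = 0, child_sex = "male",
                        dp_child = 30L, ad_child = 15L, mq_child = 60,
                        dp_mother = 30L, ad_mother = 0L, mq_mother = 60,
                        dp_father = 30L, ad_father = 0L, mq_father = 60,
                        family_id = "fam1", evaluable = TRUE) {
  tibble::tibble(
    family_id = family_id, chrom = chrom, pos = pos, ref_allele = ref,
    alt_allele = alt, gene = gene, consequence = consequence, mpc = mpc,
    gnomad_nonneuro_af = af, child_sex = child_sex,
    dp_child = dp_child, ad_child = ad_child, mq_child = mq_child,
    dp_mother = dp_mother, ad_mother = ad_mother, mq_mother = mq_mother,
    dp_father = dp_father, ad_father = ad_father, mq_father = mq_father,
    evaluable = evaluable
  )
}

# a tiny VCF for one trio: a clean de novo (the KDM5B stop-gain), a
# biallelic site with two ALT alleles, and a site with missing child AD
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=Gene.refGene,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=MPC,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=gnomAD_nonneuro_AF,Number=1,Type=Float,Description=\"a\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "fam1.p1", "fam1.mo", "fam1.fa", sep = "\t"),
    paste("chr1", "202704703", ".", "G", "A", ".", "PASS",
          "Gene.refGene=KDM5B;ExonicFunc.refGene=stopgain;gnomAD_nonneuro_AF=1.12e-5",
          "GT:DP:AD:MQ",
          "0/1:30:15,15:60", "0/0:32:32,0:60", "0/0:28:28,0:60", sep = "\t"),
    paste("chr2", "5000", ".", "C", "T,G", ".", "PASS",
          "Gene.refGene=GENEM;ExonicFunc.refGene=nonsynonymous_SNV;MPC=2.5;gnomAD_nonneuro_AF=0",
          "GT:DP:AD:MQ",
          "1/2:40:0,20,20:58", "0/0:35:35,0,0:58", "0/0:36:36,0,0:58",
          sep = "\t"),
    paste("chr3", "7000", ".", "A", "G", ".", "PASS",
          "Gene.refGene=GENEX;ExonicFunc.refGene=synonymous_SNV;gnomAD_nonneuro_AF=0",
          "GT:DP:MQ",
          "0/1:30:60", "0/0:30:60", "0/0:30:60", sep = "\t")
  )
  writeLines(lines, path)
  path
}

write_test_ped <- function(path) {
  writeLines(c(
    "fam1 fam1.p1 fam1.fa fam1.mo 1 2",
    "fam1 fam1.fa 0 0 1 1",
    "fam1 fam1.mo 0 0 2 1"
  ), path)
  path
}
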