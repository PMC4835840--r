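# Shared fixtures, all built in code at test time.

toy_genome <- function() {
  Biostrings::DNAStringSet(c(chr1 = "ACGTA", chr2 = "TTACGGA"))
}

write_tab_variants <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A small VCF 4.1 file with one multi-allelic record.
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.1",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tC\tA\t50\tPASS\t.",
    "chr2\t55\t.\tG\tT,C\t99\tPASS\t."
  ), path)
  path
}

# Transcripts: one + transcript and one - transcript on chr1, overlapping
# in [150, 200]; nothing on chr2.
toy_transcripts <- function() {
  GenomicRanges::GRanges(c("chr1", "chr1"),
                         IRanges::IRanges(c(100, 150), c(200, 260)),
                         strand = c("+", "-"),
                         name = c("txA", "txB"))
}

# An annotated-looking cohort built directly (bypassing the genome) for
# strand-bias tests: `n_plus` C>A SBS with pyrimidine ref on "+" transcripts
# (non-transcribed) and `n_minus` with ref G on "+" transcripts (transcribed).
stranded_cohort <- function(n_nontx, n_tx, sbs6 = "C>A") {
  ref_pyr <- substr(sbs6, 1, 1)
  alt_pyr <- substr(sbs6, 3, 3)
  n <- n_nontx + n_tx
  x <- cohort(chrom = rep("chr1", n), pos = seq_len(n) + 10L,
              ref = c(rep(ref_pyr, n_nontx),
                      rep(chartr("CT", "GA", ref_pyr), n_tx)),
              alt = c(rep(alt_pyr, n_nontx),
                      rep(chartr("ACGT", "TGCA", alt_pyr), n_tx)),
              sample_id = rep("S1", n))
  x$variant_type <- rep("SNP", n)
  x$context <- NA_character_
  x$strand <- rep("+", n)
  x$sbs6 <- rep(sbs6, n)
  x$class96 <- rep(paste0("A[", sbs6, "]A"), n)
  x
}
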