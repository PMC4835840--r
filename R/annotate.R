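#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA into an uppercase [Biostrings::DNAStringSet];
#' contig names are truncated at the first whitespace, matching FASTA index
#' conventions.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Match a chromosome label to a genome/GRanges contig name, tolerating a
# missing or extra "chr" prefix. Returns NA when no contig matches.
.match_contig <- function(chrom, contigs) {
  hit <- match(chrom, contigs)
  alt <- ifelse(startsWith(chrom, "chr"), sub("^chr", "", chrom),
                paste0("chr", chrom))
  ifelse(is.na(hit), match(alt, contigs), hit)
}

#' Fetch the sequence context around a genomic position
#'
#' Returns the `2 * flank + 1` bases of the plus strand centred on `pos`,
#' uppercase; positions beyond the contig ends are padded with `N`.
#'
#' @param genome A `DNAStringSet` (see [read_genome()]).
#' @param chrom Contig name (a missing/extra `"chr"` prefix is tolerated).
#' @param pos 1-based position.
#' @param flank Number of bases on each side (default 1, the trinucleotide
#'   context).
#' @return A character string of length `2 * flank + 1`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTA"))
#' fetch_context(g, "chr1", 3)      # "CGT"
#' fetch_context(g, "chr1", 1)      # "NAC"
#' @export
fetch_context <- function(genome, chrom, pos, flank = 1L) {
  stopifnot(flank >= 1L)
  i <- .match_contig(chrom, names(genome))
  if (is.na(i))
    stop("contig not found in genome: ", chrom)
  len <- Biostrings::width(genome)[i]
  if (pos < 1L || pos > len)
    stop("position ", pos, " outside contig ", chrom, " (length ", len, ")")
  lo <- max(1L, pos - flank); hi <- min(len, pos + flank)
  s <- toupper(as.character(Biostrings::subseq(genome[[i]], lo, hi)))
  paste0(strrep("N", lo - (pos - flank)), s, strrep("N", (pos + flank) - hi))
}

#' Read transcript models
#'
#' Reads a stranded interval table describing transcripts: a 6-column BED
#' (strand in column 6, via \pkg{rtracklayer}) or a refGene-style
#' tab-delimited table with columns `name`, `chrom`, `strand`, `txStart`,
#' `txEnd` (0-based starts, as in UCSC tables). Only the interval and strand
#' are used downstream; exon structure is not needed for strand assignment.
#'
#' @param path Path to the file.
#' @param format `"auto"`, `"bed"` or `"refgene"`.
#' @return A [GenomicRanges::GRanges] with strand set.
#' @export
read_transcripts <- function(path, format = c("auto", "bed", "refgene")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "refgene"
  }
  if (format == "bed")
    return(rtracklayer::import(path, format = "BED"))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "strand", "txStart", "txEnd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("refGene-style table is missing column(s): ",
         paste(miss, collapse = ", "))
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$txStart + 1L, df$txEnd),
                         strand = df$strand, name = df$name)
}

#' Assign transcript strand to variants
#'
#' For each variant position, reports `"+"` or `"-"` when all overlapping
#' transcripts agree on strand, `"ambiguous"` when transcripts on both
#' strands overlap it, and `"unknown"` when no transcript overlaps.
#'
#' @param x A `mut_cohort` data.frame.
#' @param transcripts A stranded `GRanges` (see [read_transcripts()]).
#' @return Character vector, one entry per variant.
#' @export
assign_strand <- function(x, transcripts) {
  if (!nrow(x)) return(character(0))
  tx_chrom <- as.character(GenomicRanges::seqnames(transcripts))
  idx <- .match_contig(x$chrom, unique(tx_chrom))
  chrom <- ifelse(is.na(idx), x$chrom, unique(tx_chrom)[idx])
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(x$pos, x$pos))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, transcripts,
                                                       ignore.strand = TRUE))
  st <- as.character(GenomicRanges::strand(transcripts))[S4Vectors::subjectHits(hits)]
  keep <- st %in% c("+", "-")
  by_var <- split(st[keep], S4Vectors::queryHits(hits)[keep])
  out <- rep("unknown", nrow(x))
  for (k in names(by_var)) {
    u <- unique(by_var[[k]])
    out[as.integer(k)] <- if (length(u) == 1L) u else "ambiguous"
  }
  out
}

#' Annotate a cohort with sequence context, strand and mutation class
#'
#' For every single-base substitution, retrieves the plus-strand sequence
#' context from the reference genome, assigns transcript strand, and derives
#' the pyrimidine-normalized 6-type and 96-type mutation classes. Non-SBS
#' variants receive their `variant_type` only. Variants whose stated
#' reference allele disagrees with the genome are left unclassified and
#' counted in a warning (this usually indicates a wrong genome build).
#'
#' @param x A `mut_cohort` data.frame.
#' @param genome A `DNAStringSet` (see [read_genome()]).
#' @param transcripts Optional stranded `GRanges`; when `NULL`, strand is
#'   `"unknown"` for all variants.
#' @param flank Context half-width (default 1 for trinucleotides).
#' @return The cohort with columns `variant_type`, `context` (plus-strand),
#'   `strand`, `sbs6`, `class96` appended; input order preserved.
#' @export
annotate_cohort <- function(x, genome, transcripts = NULL, flank = 1L) {
  x <- validate_cohort(as.data.frame(x))
  n <- nrow(x)
  x$variant_type <- if (n) variant_type(x$ref, x$alt) else character(0)
  x$context <- rep(NA_character_, n)
  x$strand <- if (is.null(transcripts) || !n) rep("unknown", n)
              else assign_strand(x, transcripts)
  x$sbs6 <- rep(NA_character_, n)
  x$class96 <- rep(NA_character_, n)
  is_snp <- which(x$variant_type == "SNP")
  if (length(is_snp)) {
    ctx <- vapply(is_snp, function(i) {
      fetch_context(genome, x$chrom[i], x$pos[i], flank)
    }, character(1))
    x$context[is_snp] <- ctx
    mid_pos <- flank + 1L
    tri <- paste0(substr(ctx, mid_pos - 1L, mid_pos - 1L),
                  substr(ctx, mid_pos, mid_pos),
                  substr(ctx, mid_pos + 1L, mid_pos + 1L))
    mid <- substr(tri, 2L, 2L)
    ok <- mid == toupper(x$ref[is_snp])
    if (any(!ok))
      warning(sum(!ok), " variant(s) have a reference allele that does not ",
              "match the genome and were left unclassified")
    if (any(ok)) {
      idx <- is_snp[ok]
      cl <- classify_sbs(x$ref[idx], x$alt[idx], tri[ok])
      x$sbs6[idx] <- cl$sbs6
      x$class96[idx] <- cl$class96
    }
  }
  validate_cohort(x)
}
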