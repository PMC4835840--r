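#' Read a polymorphism database
#'
#' Polymorphism lists are used to remove likely germline variants from
#' somatic call sets. Two formats are accepted: VCF (position, ref, alt,
#' with an optional `AF` INFO tag carrying the population allele frequency)
#' and 4/5-column tab-delimited tables (`chrom`, `pos`, `ref`, `alt`
#' [, `freq`]) with a header. A database without frequencies behaves like a
#' dbSNP identifier list: any exact match removes the variant.
#'
#' @param path Path to the file.
#' @param format `"auto"`, `"vcf"` or `"tab"`.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `freq`
#'   (`NA` when absent) and attribute `has_freq`.
#' @export
read_polymorphism_db <- function(path, format = c("auto", "vcf", "tab")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("\\.vcf(\\.gz)?$", path) ||
                  startsWith(first, "##fileformat=VCF")) "vcf" else "tab"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- if (nrow(fix)) vcfR::extract.info(v, "AF") else character(0)
    alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(fix)), lengths(alt_list))
    freq <- suppressWarnings(as.numeric(info))[idx]
    db <- data.frame(chrom = fix$CHROM[idx],
                     pos = as.integer(fix$POS)[idx],
                     ref = fix$REF[idx], alt = unlist(alt_list),
                     freq = if (length(idx)) freq else numeric(0),
                     stringsAsFactors = FALSE)
    attr(db, "has_freq") <- any(!is.na(db$freq))
    return(db)
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          quote = "")
  if (ncol(df) < 4L)
    stop("polymorphism table needs at least 4 columns (chrom, pos, ref, alt): ",
         path)
  pos <- suppressWarnings(as.integer(df[[2]]))
  if (nrow(df) && anyNA(pos))
    stop("unparseable position at line ", which(is.na(pos))[1] + 1L,
         " of ", path)
  freq <- if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5]]))
          else rep(NA_real_, nrow(df))
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]: ", path)
  db <- data.frame(chrom = df[[1]], pos = pos, ref = toupper(df[[3]]),
                   alt = toupper(df[[4]]), freq = freq,
                   stringsAsFactors = FALSE)
  attr(db, "has_freq") <- ncol(df) >= 5L
  db
}

#' Read genomic regions from BED
#'
#' Reads an interval file (e.g. segmental-duplication regions) as a
#' `GRanges` via \pkg{rtracklayer}.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges].
#' @export
read_regions <- function(path) {
  rtracklayer::import(path, format = "BED")
}

.variant_key <- function(chrom, pos, ref, alt, position_only = FALSE) {
  chrom <- sub("^chr", "", chrom)
  if (position_only) paste(chrom, pos, sep = ":")
  else paste(chrom, pos, toupper(ref), toupper(alt), sep = ":")
}

#' Filter variants against polymorphism databases and region sets
#'
#' A variant is removed when (a) it exactly matches an entry of a
#' frequency-less database (dbSNP-style: any match removes), (b) it matches
#' an entry whose population allele frequency exceeds `max_freq` in a
#' frequency-bearing database, or (c) its position lies inside any interval
#' of `regions` (e.g. segmental duplications). Matching requires allele
#' identity (chrom, pos, ref, alt) unless `position_only` is set. Filtering
#' is idempotent: running it again on the kept set removes nothing.
#'
#' @param x A `mut_cohort` data.frame.
#' @param dbs A list of polymorphism databases ([read_polymorphism_db()]);
#'   may be named for the report.
#' @param regions Optional `GRanges` of excluded intervals.
#' @param max_freq Frequency threshold for frequency-bearing databases
#'   (default 0.01, i.e. variants common in human populations at > 1\%).
#' @param position_only Match databases on chrom+pos only (for lists that
#'   lack alleles).
#' @return A list with elements `kept`, `removed` (both cohorts) and
#'   `report` (named integer vector of removal counts per criterion).
#' @export
filter_variants <- function(x, dbs = list(), regions = NULL, max_freq = 0.01,
                            position_only = FALSE) {
  x <- validate_cohort(as.data.frame(x))
  n <- nrow(x)
  drop <- rep(FALSE, n)
  report <- integer(0)
  if (length(dbs) && is.null(names(dbs)))
    names(dbs) <- paste0("db", seq_along(dbs))
  keys <- .variant_key(x$chrom, x$pos, x$ref, x$alt, position_only)
  for (nm in names(dbs)) {
    db <- dbs[[nm]]
    dkeys <- .variant_key(db$chrom, db$pos, db$ref, db$alt, position_only)
    if (isTRUE(attr(db, "has_freq"))) {
      hit <- !drop & keys %in% dkeys[!is.na(db$freq) & db$freq > max_freq]
    } else {
      hit <- !drop & keys %in% dkeys
    }
    report[nm] <- sum(hit)
    drop <- drop | hit
  }
  if (!is.null(regions) && n) {
    rchrom <- unique(as.character(GenomicRanges::seqnames(regions)))
    idx <- .match_contig(x$chrom, rchrom)
    chrom <- ifelse(is.na(idx), x$chrom, rchrom[idx])
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(x$pos, x$pos))
    ov <- suppressWarnings(GenomicRanges::countOverlaps(q, regions,
                                                        ignore.strand = TRUE))
    hit <- !drop & ov > 0L
    report["regions"] <- sum(hit)
    drop <- drop | hit
  } else if (!is.null(regions)) {
    report["regions"] <- 0L
  }
  report["total_removed"] <- sum(drop)
  kept <- x[!drop, , drop = FALSE]; rownames(kept) <- NULL
  removed <- x[drop, , drop = FALSE]; rownames(removed) <- NULL
  list(kept = validate_cohort(kept), removed = validate_cohort(removed),
       report = report)
}
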