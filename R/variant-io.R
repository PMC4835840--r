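#' Supported tab-delimited header dialects
#'
#' Variant tables from different sources name the four required columns
#' (chromosome, 1-based start position, reference allele, alternate allele)
#' differently. This table maps each supported dialect to its column names;
#' matching is case-sensitive. The sample-identifier column is optional in
#' every dialect.
#'
#' @return A named list; each element is a named character vector with
#'   entries `chrom`, `pos`, `ref`, `alt`, `sample`.
#' @examples
#' names(variant_dialects())
#' variant_dialects()$icgc
#' @export
variant_dialects <- function() {
  list(
    generic = c(chrom = "Chr", pos = "Start", ref = "Ref", alt = "Alt",
                sample = "SampleID"),
    icgc = c(chrom = "chromosome", pos = "chromosome_start",
             ref = "reference_genome_allele", alt = "mutated_to_allele",
             sample = "icgc_donor_id"),
    tcga = c(chrom = "Chromosome", pos = "Start_Position",
             ref = "Reference_Allele", alt = "Tumor_Seq_Allele2",
             sample = "Tumor_Sample_Barcode"),
    cosmic = c(chrom = "Chromosome", pos = "Genome_start",
               ref = "GENOMIC_WT_ALLELE", alt = "GENOMIC_MUT_ALLELE",
               sample = "Sample_name")
  )
}

.required_fields <- c(chrom = "chromosome", pos = "start position",
                      ref = "reference allele", alt = "alternate allele")

#' Build a variant cohort
#'
#' A cohort is a plain `data.frame` holding one variant per row with the
#' required columns `chrom`, `pos` (1-based), `ref`, `alt`, `sample_id`;
#' any further columns are pass-through annotations. Coordinates follow the
#' VCF/ICGC convention: 1-based, fully closed. Indels are represented with a
#' `"-"` allele or length-mismatched alleles.
#'
#' @param chrom,ref,alt Character vectors.
#' @param pos Integer vector of 1-based positions (all `>= 1`).
#' @param sample_id Character vector of sample identifiers.
#' @param extra Optional data.frame of pass-through columns.
#' @return A data.frame of class `mut_cohort`.
#' @export
cohort <- function(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), sample_id = character(), extra = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   sample_id = as.character(sample_id),
                   stringsAsFactors = FALSE)
  if (!is.null(extra) && ncol(extra) > 0L)
    df <- cbind(df, extra)
  validate_cohort(df)
}

#' @rdname cohort
#' @param x A data.frame with the required cohort columns.
#' @export
validate_cohort <- function(x) {
  miss <- setdiff(c("chrom", "pos", "ref", "alt", "sample_id"), names(x))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(is.na(x$pos)) || any(x$pos < 1L))
      stop("cohort positions must be 1-based integers >= 1")
    if (any(!nzchar(x$ref)) || any(!nzchar(x$alt)))
      stop("cohort ref and alt alleles must be non-empty")
    if (any(x$ref == x$alt))
      stop("cohort ref and alt alleles must differ")
  }
  class(x) <- unique(c("mut_cohort", class(x)))
  x
}

#' Variant type from allele pair
#'
#' Classifies an allele pair as `"SNP"` (both single bases in A/C/G/T),
#' `"INS"` (reference `"-"` or shorter than the alternate), `"DEL"`
#' (alternate `"-"` or shorter than the reference) or `"OTHER"`.
#'
#' @param ref,alt Character vectors of alleles over `{A,C,G,T,-}`.
#' @return Character vector of types.
#' @export
variant_type <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  snp <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  ins <- !snp & (ref == "-" | nchar(alt) > nchar(ref))
  del <- !snp & !ins & (alt == "-" | nchar(ref) > nchar(alt))
  out <- rep("OTHER", length(ref))
  out[snp] <- "SNP"; out[ins] <- "INS"; out[del] <- "DEL"
  out
}

#' Read a variant table
#'
#' Reads VCF 4.1 files (via \pkg{vcfR}) or tab-delimited variant tables in
#' any of the dialects returned by [variant_dialects()]. Multi-allelic VCF
#' records are decomposed into one variant per alternate allele.
#' Unrecognised columns of tab files are preserved in input order after the
#' required ones.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default: by extension/content), `"vcf"` or `"tab"`.
#' @param sample_id Sample identifier to assign when the file carries no
#'   sample column; defaults to the file name without extension.
#' @return A `mut_cohort` data.frame (see [cohort()]).
#' @export
read_variants <- function(path, format = c("auto", "tab", "vcf"),
                          sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("\\.vcf(\\.gz)?$", path) ||
                  startsWith(first, "##fileformat=VCF")) "vcf" else "tab"
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.(vcf|tsv|txt|tab)(\\.gz)?$", "", basename(path))
  if (format == "vcf") .read_vcf(path, sample_id) else .read_tab(path, sample_id)
}

.read_vcf <- function(path, sample_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(cohort())
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos))
    stop("unparseable POS at VCF record ", which(is.na(pos))[1])
  extra <- data.frame(ID = fix$ID[idx], FILTER = fix$FILTER[idx],
                      stringsAsFactors = FALSE)
  extra$ID[is.na(extra$ID)] <- "."
  extra$FILTER[is.na(extra$FILTER)] <- "."
  cohort(chrom = fix$CHROM[idx], pos = pos[idx], ref = fix$REF[idx],
         alt = unlist(alt_list), sample_id = rep(sample_id, length(idx)),
         extra = extra)
}

.read_tab <- function(path, sample_id) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  header <- names(df)
  match_one <- function(field) {
    for (d in variant_dialects()) {
      if (d[[field]] %in% header) return(d[[field]])
    }
    NA_character_
  }
  cols <- vapply(c("chrom", "pos", "ref", "alt"), match_one, character(1))
  if (anyNA(cols)) {
    missing <- .required_fields[names(cols)[is.na(cols)]]
    stop("no recognised header for required field(s): ",
         paste(missing, collapse = ", "),
         " (see variant_dialects() for supported, case-sensitive names)")
  }
  sample_col <- NA_character_
  for (d in variant_dialects()) {
    if (d[["sample"]] %in% header) { sample_col <- d[["sample"]]; break }
  }
  pos <- suppressWarnings(as.integer(df[[cols["pos"]]]))
  if (nrow(df) && anyNA(pos))
    stop("unparseable position at line ", which(is.na(pos))[1] + 1L,
         " of ", path)
  used <- c(unname(cols), if (!is.na(sample_col)) sample_col)
  extra <- df[, setdiff(header, used), drop = FALSE]
  cohort(chrom = df[[cols["chrom"]]], pos = pos, ref = df[[cols["ref"]]],
         alt = df[[cols["alt"]]],
         sample_id = if (is.na(sample_col)) rep(sample_id, nrow(df))
                     else df[[sample_col]],
         extra = extra)
}

#' Split a cohort by sample
#'
#' Partitions a cohort into one cohort per distinct sample identifier,
#' preserving variant order within each sample. The union of the outputs is
#' exactly the input.
#'
#' @param x A `mut_cohort` data.frame.
#' @param id_column Column holding the sample identifier (default
#'   `"sample_id"`).
#' @return A named list of `mut_cohort` objects, in order of first appearance.
#' @export
split_by_sample <- function(x, id_column = "sample_id") {
  if (!id_column %in% names(x))
    stop("id column not found: ", id_column)
  ids <- as.character(x[[id_column]])
  out <- lapply(unique(ids), function(s) {
    y <- x[ids == s, , drop = FALSE]
    rownames(y) <- NULL
    validate_cohort(y)
  })
  names(out) <- unique(ids)
  out
}

#' Write a cohort as a tab-delimited variant table
#'
#' Writes the generic dialect (`Chr`, `Start`, `Ref`, `Alt`, `SampleID`)
#' followed by any extra columns in their original order, so that
#' `read_variants()` on the result reproduces the cohort field-for-field.
#'
#' @param x A `mut_cohort` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path) {
  x <- validate_cohort(as.data.frame(x))
  req <- c("chrom", "pos", "ref", "alt", "sample_id")
  out <- x[, c(req, setdiff(names(x), req)), drop = FALSE]
  names(out)[seq_len(5)] <- c("Chr", "Start", "Ref", "Alt", "SampleID")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
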