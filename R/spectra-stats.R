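#' Build a mutation count matrix
#'
#' The 96 x samples non-negative count matrix used throughout the package,
#' with rows in the canonical class order of [sbs96_classes()]. Column sums
#' equal each sample's number of classifiable SBS.
#'
#' @param counts Numeric matrix, 96 rows.
#' @param samples Optional column names.
#' @return The validated matrix (rownames set to the canonical labels).
#' @export
mutation_matrix <- function(counts, samples = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 96L)
    stop("a mutation matrix has exactly 96 rows")
  if (any(counts < 0))
    stop("mutation counts must be non-negative")
  if (!is.null(rownames(counts))) {
    ord <- match(sbs96_classes(), rownames(counts))
    if (anyNA(ord))
      stop("unrecognised or missing 96-class row label(s): ",
           paste(setdiff(sbs96_classes(), rownames(counts)), collapse = ", "))
    counts <- counts[ord, , drop = FALSE]
  } else {
    rownames(counts) <- sbs96_classes()
  }
  if (!is.null(samples)) colnames(counts) <- samples
  counts
}

#' Count mutation spectra in an annotated cohort
#'
#' Tallies, per sample: the overall variant-type distribution (SBS and
#' indels), the 6-type SBS counts and the 96-class trinucleotide-context
#' matrix. Every classifiable SBS is counted exactly once; SBS whose context
#' contains `N` appear in the 6-type counts but not in the 96-class matrix.
#' When `annotation_column` names an existing column (e.g. a functional
#' annotation carried through from an external annotator), a per-category
#' count table is included.
#'
#' @param x An annotated cohort (see [annotate_cohort()]).
#' @param annotation_column Optional name of a pass-through annotation
#'   column to summarise.
#' @return A list with `matrix96` (96 x samples counts), `sbs6` (6 x samples
#'   counts), `type_distribution` (variant types x samples) and, when
#'   requested and present, `annotation_summary`.
#' @export
count_spectra <- function(x, annotation_column = NULL) {
  x <- as.data.frame(x)
  if (!"variant_type" %in% names(x))
    stop("cohort is not annotated; run annotate_cohort() first")
  samples <- unique(x$sample_id)
  if (!length(samples)) samples <- character(0)
  sfac <- factor(x$sample_id, levels = samples)

  m96 <- table(factor(x$class96, levels = sbs96_classes()), sfac)
  m96 <- matrix(as.integer(m96), nrow = 96L,
                dimnames = list(sbs96_classes(), samples))
  m6 <- table(factor(x$sbs6, levels = sbs6_types()), sfac)
  m6 <- matrix(as.integer(m6), nrow = 6L,
               dimnames = list(sbs6_types(), samples))
  types <- sort(unique(x$variant_type))
  td <- table(factor(x$variant_type, levels = types), sfac)
  td <- matrix(as.integer(td), nrow = length(types),
               dimnames = list(types, samples))
  out <- list(matrix96 = m96, sbs6 = m6, type_distribution = td)
  if (!is.null(annotation_column)) {
    if (!annotation_column %in% names(x)) {
      message("annotation column '", annotation_column,
              "' not present; summary skipped")
    } else {
      cats <- sort(unique(as.character(x[[annotation_column]])))
      an <- table(factor(x[[annotation_column]], levels = cats), sfac)
      out$annotation_summary <- matrix(as.integer(an), nrow = length(cats),
                                       dimnames = list(cats, samples))
    }
  }
  out
}

#' Transcriptional strand bias of SBS types
#'
#' Compares mutation counts between the transcribed (template) and
#' non-transcribed (coding) strands of genes. Only variants with an
#' unambiguous transcript strand are used. A mutation is counted on the
#' non-transcribed strand when the strand carrying the pyrimidine of the
#' mutated base pair equals the transcript strand (the stranded-catalog
#' convention). For each type, a chi-squared goodness-of-fit test against
#' equal counts (1 df, no continuity correction) is applied, followed by
#' Benjamini-Hochberg correction across the types tested at the chosen
#' level.
#'
#' @param x An annotated cohort with a `strand` column.
#' @param level `"6"` (default) or `"96"`: test the 6 SBS types or the 96
#'   context classes.
#' @return A data.frame with one row per type: `type`, `n_transcribed`,
#'   `n_nontranscribed`, `chi2`, `p`, `q`. Types with zero total have `NA`
#'   statistics.
#' @export
strand_bias <- function(x, level = c("6", "96")) {
  level <- match.arg(level)
  x <- as.data.frame(x)
  if (!all(c("strand", "sbs6") %in% names(x)))
    stop("cohort lacks strand/class annotations; run annotate_cohort() ",
         "with transcripts")
  use <- x$strand %in% c("+", "-") & !is.na(x$sbs6)
  types <- if (level == "6") sbs6_types() else sbs96_classes()
  cls <- if (level == "6") x$sbs6 else x$class96
  use <- use & !is.na(cls)
  # pyrimidine of the pair sits on "+" iff the stated ref base is C or T
  pyr_strand <- ifelse(toupper(x$ref) %in% c("C", "T"), "+", "-")
  nontx <- use & pyr_strand == x$strand
  tx <- use & pyr_strand != x$strand
  n_tx <- table(factor(cls[tx], levels = types))
  n_ntx <- table(factor(cls[nontx], levels = types))
  res <- strand_bias_test(as.integer(n_tx), as.integer(n_ntx))
  data.frame(type = types,
             n_transcribed = as.integer(n_tx),
             n_nontranscribed = as.integer(n_ntx),
             chi2 = res$chi2, p = res$p, q = res$q,
             stringsAsFactors = FALSE)
}

#' Chi-squared strand-bias test with BH correction
#'
#' Goodness-of-fit of observed (transcribed, non-transcribed) counts against
#' a 50/50 expectation: `chi2 = (a - b)^2 / (a + b)` with 1 degree of
#' freedom. Types with zero total are skipped (`NA`). Benjamini-Hochberg
#' adjusted p-values are computed across the tested types.
#'
#' @param n_transcribed,n_nontranscribed Integer vectors of counts.
#' @return A list with numeric vectors `chi2`, `p`, `q`.
#' @examples
#' strand_bias_test(30, 10)  # chi2 = 10, p ~ 1.565e-3
#' @export
strand_bias_test <- function(n_transcribed, n_nontranscribed) {
  a <- as.numeric(n_transcribed); b <- as.numeric(n_nontranscribed)
  tot <- a + b
  chi2 <- ifelse(tot > 0, (a - b)^2 / tot, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(chi2 = chi2, p = p, q = q)
}

#' Chromosomal distribution of SBS
#'
#' Counts classifiable SBS per chromosome and computes the Pearson
#' correlation between counts and chromosome lengths.
#'
#' @param x An annotated cohort.
#' @param chrom_lengths Named numeric vector of chromosome lengths in base
#'   pairs (e.g. from a FASTA index); chromosomes absent from the cohort
#'   count zero.
#' @return A list with `table` (data.frame `chrom`, `count`, `length`) and
#'   `r` (Pearson correlation; `NA` with fewer than 3 chromosomes).
#' @export
chrom_distribution <- function(x, chrom_lengths) {
  x <- as.data.frame(x)
  sbs <- x[!is.na(x$sbs6), , drop = FALSE]
  chroms <- names(chrom_lengths)
  idx <- .match_contig(sbs$chrom, chroms)
  cnt <- table(factor(chroms[idx], levels = chroms))
  tab <- data.frame(chrom = chroms, count = as.integer(cnt),
                    length = as.numeric(chrom_lengths),
                    stringsAsFactors = FALSE)
  r <- if (nrow(tab) >= 3L && stats::sd(tab$count) > 0 &&
           stats::sd(tab$length) > 0)
    stats::cor(tab$count, tab$length) else NA_real_
  list(table = tab, r = r)
}

#' Pool samples of a mutation matrix
#'
#' Row-wise sum across all sample columns, returned as a single-column
#' mutation matrix named `"Pool"`. Pooling is idempotent.
#'
#' @param m A mutation matrix ([mutation_matrix()]).
#' @return A 96 x 1 matrix with column `"Pool"`.
#' @export
pool_samples <- function(m) {
  m <- mutation_matrix(m)
  mutation_matrix(matrix(rowSums(m), ncol = 1,
                         dimnames = list(rownames(m), "Pool")))
}
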