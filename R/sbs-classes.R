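#' Canonical SBS mutation classes
#'
#' Somatic single-base substitutions are summarised after pyrimidine
#' normalization: each substitution is expressed with respect to the strand
#' carrying the pyrimidine (C or T) reference base, giving six base-change
#' types, and 96 classes once the immediate 5' and 3' neighbours are added.
#'
#' `sbs6_types()` returns the six substitution types. `sbs96_classes()`
#' returns the 96 class labels in the package's canonical order: the six
#' substitution blocks `C>A, C>G, C>T, T>A, T>C, T>G`, and within each block
#' the 16 trinucleotide contexts ordered A, C, G, T by upstream base first,
#' then downstream base. Labels use the COSMIC-style form `"A[C>A]A"`.
#'
#' @return A character vector of length 6 (`sbs6_types`) or 96
#'   (`sbs96_classes`).
#' @examples
#' sbs6_types()
#' head(sbs96_classes())
#' @export
sbs6_types <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' @rdname sbs6_types
#' @export
sbs96_classes <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(sbs6_types(), function(s) {
    as.vector(t(outer(bases, bases, function(u, d) {
      paste0(u, "[", s, "]", d)
    })))
  }), use.names = FALSE)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A, C, G, T, N. Used for
#' pyrimidine normalization of substitution classes; for whole-sequence work
#' use [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("AGC", "T"))
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""),
         character(1))
}

#' Classify single-base substitutions into pyrimidine-normalized classes
#'
#' Assigns each substitution its 6-type (`C>A` ... `T>G`) and 96-type
#' (trinucleotide-context) class. Substitutions whose reference base is a
#' purine (A or G) are reverse-complemented together with their context so
#' that the reported class always carries a pyrimidine reference base.
#'
#' @param ref Character vector of reference bases (plus strand).
#' @param alt Character vector of alternate bases (plus strand).
#' @param context Character vector of plus-strand trinucleotides whose middle
#'   base must equal `ref`. An `N` at a flank makes the 96-type class `NA`
#'   while the 6-type is still reported; an `N` as the middle base makes both
#'   `NA`.
#' @return A data.frame with columns `sbs6`, `context` (pyrimidine-normalized
#'   trinucleotide) and `class96`.
#' @examples
#' classify_sbs("G", "T", "AGC")   # G[C>A]T after reverse complement
#' classify_sbs("C", "T", "ACG")   # A[C>T]G, already pyrimidine
#' @export
classify_sbs <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(ref == alt & !bad))
    stop("classify_sbs(): ref and alt must differ")
  if (any(nchar(context) != 3L))
    stop("classify_sbs(): context must be a trinucleotide")
  mid <- substr(context, 2L, 2L)
  mismatch <- !bad & mid != "N" & mid != ref
  if (any(mismatch))
    stop("classify_sbs(): reference base does not match the middle of the ",
         "context for ", sum(mismatch), " variant(s); check the genome build")

  purine <- ref %in% c("A", "G")
  ref_n <- ifelse(purine, chartr("AG", "TC", ref), ref)
  alt_n <- ifelse(purine, chartr("ACGT", "TGCA", alt), alt)
  ctx_n <- context
  ctx_n[purine] <- reverse_complement(context[purine])

  sbs6 <- paste0(ref_n, ">", alt_n)
  has_n <- grepl("N", ctx_n, fixed = TRUE)
  class96 <- paste0(substr(ctx_n, 1L, 1L), "[", sbs6, "]", substr(ctx_n, 3L, 3L))
  class96[has_n] <- NA_character_
  sbs6[bad] <- NA_character_
  class96[bad] <- NA_character_
  ctx_n[bad] <- NA_character_
  data.frame(sbs6 = sbs6, context = ctx_n, class96 = class96,
             stringsAsFactors = FALSE)
}
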