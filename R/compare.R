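#' Cosine similarity of two non-negative vectors
#'
#' `a . b / (||a|| ||b||)`; for non-negative inputs the value lies in
#' [0, 1], where 0 means disjoint support and 1 identical direction. Scale
#' invariant: `cosine_sim(c * a, b) == cosine_sim(a, b)` for `c > 0`.
#'
#' @param a,b Numeric vectors of equal length.
#' @return The cosine, or `NA` when either vector is all zero.
#' @examples
#' cosine_sim(c(1, 1, 0), c(1, 0, 0))  # 1 / sqrt(2)
#' @export
cosine_sim <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Read a signature matrix
#'
#' Reads a tab-delimited signature matrix: first column the 96 class labels
#' (e.g. `"A[C>A]A"`), remaining columns one signature each. Rows are
#' reordered to the canonical order of [sbs96_classes()]; a missing or
#' unrecognised class label is an error.
#'
#' @param path Path to the TSV file.
#' @return A 96 x signatures numeric matrix.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- labels
  canonicalize_signatures(m)
}

#' Reorder a signature matrix to the canonical 96-class order
#'
#' @param m Numeric matrix with 96-class row labels.
#' @return The matrix with rows in [sbs96_classes()] order.
#' @export
canonicalize_signatures <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)))
    stop("signature matrix must carry 96-class row labels")
  bad <- setdiff(rownames(m), sbs96_classes())
  missing <- setdiff(sbs96_classes(), rownames(m))
  if (length(bad) || length(missing))
    stop("signature matrix class labels do not form the 96 canonical ",
         "classes; unrecognised: [", paste(bad, collapse = ", "),
         "], missing: [", paste(missing, collapse = ", "), "]")
  if (any(m < 0))
    stop("signature values must be non-negative")
  m[sbs96_classes(), , drop = FALSE]
}

#' Compare extracted signatures with a reference set
#'
#' Computes the full cosine-similarity matrix between extracted and
#' reference signatures after reordering both to the canonical 96-class
#' order, and flags matches above a similarity threshold. A cosine value
#' above 0.9 is conventionally considered a good match.
#'
#' @param extracted,reference Numeric matrices (96 x signatures) with
#'   96-class row labels, or a `mutspec_nmf` object for `extracted` (its
#'   `W` is used).
#' @param threshold Match threshold; strictly greater-than (default 0.9).
#' @return An object of class `signature_similarity`: list with
#'   `similarity` (extracted x reference cosines), `matches` (named list of
#'   matching reference names per extracted signature) and `threshold`.
#' @export
compare_signatures <- function(extracted, reference, threshold = 0.9) {
  if (inherits(extracted, "mutspec_nmf")) extracted <- extracted$W
  E <- canonicalize_signatures(extracted)
  R <- canonicalize_signatures(reference)
  sim <- matrix(NA_real_, ncol(E), ncol(R),
                dimnames = list(colnames(E), colnames(R)))
  for (i in seq_len(ncol(E)))
    for (j in seq_len(ncol(R)))
      sim[i, j] <- cosine_sim(E[, i], R[, j])
  matches <- lapply(seq_len(nrow(sim)), function(i) {
    colnames(sim)[which(!is.na(sim[i, ]) & sim[i, ] > threshold)]
  })
  names(matches) <- rownames(sim)
  structure(list(similarity = sim, matches = matches, threshold = threshold),
            class = "signature_similarity")
}

#' @export
print.signature_similarity <- function(x, ...) {
  cat("Cosine similarity (threshold ", x$threshold, "):\n", sep = "")
  print(round(x$similarity, 3))
  for (nm in names(x$matches)) {
    m <- x$matches[[nm]]
    cat(nm, "->", if (length(m)) paste(m, collapse = ", ") else "(no match)",
        "\n")
  }
  invisible(x)
}

#' Write a labelled matrix as TSV
#'
#' Writes a matrix with its row labels in a first column, the format
#' consumed by [read_signature_matrix()] and the NMF entry points.
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param label_header Header of the label column (default `"class"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, label_header = "class") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
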