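#' Simulate random mutational signatures
#'
#' Draws `n_signatures` random probability profiles over the 96 classes
#' (normalised gamma deviates, i.e. Dirichlet-distributed), resampling until
#' every pair is separated by at least `separation` in cosine distance
#' (`1 - cosine`). A sparse shape parameter concentrates each signature on
#' a minority of contexts, as real mutational signatures are.
#'
#' @param n_signatures Number of signatures.
#' @param separation Minimum pairwise cosine distance (default 0.8).
#' @param shape Gamma shape controlling sparsity (default 0.1; smaller is
#'   sparser).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling bound (default 1000).
#' @return A 96 x `n_signatures` matrix; columns sum to 1.
#' @export
simulate_signatures <- function(n_signatures, separation = 0.8, shape = 0.1,
                                seed = 1L, max_tries = 1000L) {
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    W <- matrix(stats::rgamma(96L * n_signatures, shape = shape), 96L)
    W <- sweep(W, 2L, colSums(W), "/")
    ok <- TRUE
    if (n_signatures > 1L) {
      for (i in seq_len(n_signatures - 1L))
        for (j in seq(i + 1L, n_signatures))
          if (1 - cosine_sim(W[, i], W[, j]) < separation) ok <- FALSE
    }
    if (ok) {
      dimnames(W) <- list(sbs96_classes(),
                          paste0("TrueSig", LETTERS[seq_len(n_signatures)]))
      return(W)
    }
  }
  stop("could not draw ", n_signatures, " signatures at cosine distance >= ",
       separation, " within ", max_tries, " tries")
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Generates ground-truth signatures `W`, per-sample exposures `H` and a
#' sampled 96 x samples count matrix `V`. Exposures are Dirichlet mixture
#' weights scaled by the per-sample mutation total. Under `"multinomial"`
#' noise each sample's mutations are drawn from its mixture distribution
#' (count-preserving); `"poisson"` draws each cell independently;
#' `"none"` rounds the expected counts.
#'
#' @param n_signatures,n_samples Dimensions of the simulation.
#' @param mutations_per_sample Mean mutation count per sample (default
#'   1000).
#' @param separation Minimum pairwise cosine distance between true
#'   signatures (default 0.8).
#' @param noise `"multinomial"` (default), `"poisson"` or `"none"`.
#' @param alpha Dirichlet concentration of the exposures (default 0.1;
#'   values well below 1 produce samples dominated by a single signature,
#'   as in cohorts whose tumors reflect distinct mutational processes).
#' @param seed Integer seed; runs are fully deterministic given the seed.
#' @return A list with `W` (96 x k, columns sum to 1), `H` (k x samples,
#'   columns sum to the sample totals) and `V` (96 x samples counts,
#'   a [mutation_matrix()]).
#' @export
simulate_catalog <- function(n_signatures = 3L, n_samples = 30L,
                             mutations_per_sample = 1000L, separation = 0.8,
                             noise = c("multinomial", "poisson", "none"),
                             alpha = 0.1, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_signatures >= 1L, n_samples >= 1L, mutations_per_sample >= 1L)
  W <- simulate_signatures(n_signatures, separation = separation, seed = seed)
  set.seed(seed + 1L)
  mix <- matrix(stats::rgamma(n_signatures * n_samples, shape = alpha),
                n_signatures)
  mix <- sweep(mix, 2L, colSums(mix), "/")
  H <- mix * mutations_per_sample
  samples <- sprintf("S%02d", seq_len(n_samples))
  dimnames(H) <- list(colnames(W), samples)
  P <- W %*% mix          # per-sample class probabilities
  V <- switch(noise,
    none = round(W %*% H),
    multinomial = vapply(seq_len(n_samples), function(s) {
      as.numeric(stats::rmultinom(1, mutations_per_sample, P[, s]))
    }, numeric(96L)),
    poisson = matrix(stats::rpois(96L * n_samples, lambda = W %*% H), 96L)
  )
  V <- mutation_matrix(matrix(V, 96L, dimnames = list(sbs96_classes(),
                                                      samples)))
  list(W = W, H = H, V = V)
}

# Integer class counts from a target profile by largest-remainder
# apportionment: exact total, deterministic.
.profile_counts <- function(target_profile, n_variants) {
  p <- target_profile / sum(target_profile)
  raw <- p * n_variants
  cnt <- floor(raw)
  short <- n_variants - sum(cnt)
  if (short > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(short)]] <- cnt[ord[seq_len(short)]] + 1
  }
  as.integer(cnt)
}

.parse_class96 <- function(label) {
  ok <- grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", label)
  if (!all(ok))
    stop("invalid 96-class label(s): ", paste(label[!ok], collapse = ", "))
  data.frame(up = substr(label, 1, 1), ref = substr(label, 3, 3),
             alt = substr(label, 5, 5), down = substr(label, 7, 7),
             stringsAsFactors = FALSE)
}

#' Simulate a toy genome and a variant list realizing a target spectrum
#'
#' Draws a random uniform-composition contig and places SBS variants only at
#' positions whose plus-strand trinucleotide (or its reverse complement)
#' matches the drawn mutation class, so that annotating and counting the
#' output reproduces the requested class counts exactly. The genome is
#' extended with further random sequence if a required context is missing.
#'
#' @param genome_length Initial contig length (default 10000).
#' @param target_profile Named numeric vector over 96-class labels (a subset
#'   is fine): target class proportions or counts.
#' @param n_variants Total number of variants to place.
#' @param seed Integer seed.
#' @param contig Contig name (default `"chr1"`).
#' @param sample_id Sample identifier for the variant table.
#' @return A list with `genome` (a `DNAStringSet`), `variants` (a
#'   `mut_cohort`) and `counts` (the placed per-class counts).
#' @export
simulate_variants <- function(genome_length = 10000L, target_profile,
                              n_variants, seed = 1L, contig = "chr1",
                              sample_id = "SIM1") {
  if (is.null(names(target_profile)))
    stop("target_profile must be named by 96-class labels")
  cls <- .parse_class96(names(target_profile))
  counts <- .profile_counts(target_profile, n_variants)
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
             collapse = "")
  comp <- function(b) chartr("ACGT", "TGCA", b)
  pos_all <- integer(0); ref_all <- character(0); alt_all <- character(0)
  used <- integer(0)
  for (k in seq_along(counts)) {
    need <- counts[k]
    if (need == 0L) next
    ctx <- paste0(cls$up[k], cls$ref[k], cls$down[k])
    rc <- reverse_complement(ctx)
    for (attempt in 1:20) {
      L <- nchar(g)
      tri <- substring(g, 1:(L - 2L), 3:L)
      fwd <- which(tri == ctx) + 1L
      rev <- if (rc != ctx) which(tri == rc) + 1L else integer(0)
      avail_fwd <- setdiff(fwd, used)
      avail_rev <- setdiff(rev, used)
      avail <- c(avail_fwd, avail_rev)
      if (length(avail) >= need) break
      g <- paste0(g, paste(sample(c("A", "C", "G", "T"), genome_length,
                                  replace = TRUE), collapse = ""))
    }
    if (length(avail) < need)
      stop("context ", ctx, " too rare to place ", need, " variants")
    pick <- if (length(avail) == 1L) avail else sample(avail, need)
    pick <- pick[seq_len(need)]
    on_fwd <- pick %in% avail_fwd
    used <- c(used, pick)
    pos_all <- c(pos_all, pick)
    ref_all <- c(ref_all, ifelse(on_fwd, cls$ref[k], comp(cls$ref[k])))
    alt_all <- c(alt_all, ifelse(on_fwd, cls$alt[k], comp(cls$alt[k])))
  }
  ord <- order(pos_all)
  genome <- Biostrings::DNAStringSet(stats::setNames(g, contig))
  variants <- cohort(chrom = rep(contig, length(pos_all))[ord],
                     pos = pos_all[ord], ref = ref_all[ord],
                     alt = alt_all[ord],
                     sample_id = rep(sample_id, length(pos_all)))
  names(counts) <- names(target_profile)
  list(genome = genome, variants = variants, counts = counts)
}
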