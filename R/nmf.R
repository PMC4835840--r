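#' Generalized Kullback-Leibler divergence of a factorization
#'
#' The objective minimised by the multiplicative updates:
#' `D(V || WH) = sum(V * log(V / WH) - V + WH)`, with `0 * log(0)` taken
#' as 0. Always non-negative, zero iff `WH == V`.
#'
#' @param V Non-negative data matrix.
#' @param W,H Non-negative factors.
#' @return The divergence (a single number).
#' @export
kl_divergence <- function(V, W, H) {
  WH <- W %*% H
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' One multiplicative KL update (Brunet)
#'
#' Applies one pair of multiplicative updates (H first, then W with the
#' updated H) that never increase the generalized KL divergence. A small
#' epsilon floors denominators against division by zero.
#'
#' @param V Non-negative data matrix (n x m).
#' @param W Non-negative n x k matrix.
#' @param H Non-negative k x m matrix.
#' @param eps Denominator floor (default `.Machine$double.eps`).
#' @return A list with updated `W` and `H`.
#' @export
kl_update <- function(V, W, H, eps = .Machine$double.eps) {
  WH <- W %*% H
  H <- H * crossprod(W, V / (WH + eps)) / (colSums(W) + eps)
  WH <- W %*% H
  W <- W * ((V / (WH + eps)) %*% t(H))
  W <- sweep(W, 2L, rowSums(H) + eps, "/")
  list(W = W, H = H)
}

# One NMF run from a seeded random start. Convergence follows the
# connectivity-stability criterion: every `check_every` iterations the
# dominant-signature assignment of each sample is recorded; the run stops
# once it has been unchanged for `stable_checks` consecutive checks, or at
# `max_iter`.
.nmf_run <- function(V, rank, seed, max_iter = 2000L, check_every = 10L,
                     stable_checks = 40L, eps = .Machine$double.eps) {
  set.seed(seed)
  n <- nrow(V); m <- ncol(V); mv <- mean(V)
  W <- matrix(stats::runif(n * rank) * mv, n, rank)
  H <- matrix(stats::runif(rank * m) * mv, rank, m)
  assign_prev <- integer(0)
  stable <- 0L
  iter <- 0L
  while (iter < max_iter) {
    up <- kl_update(V, W, H, eps)
    W <- up$W; H <- up$H
    iter <- iter + 1L
    if (iter %% check_every == 0L) {
      a <- max.col(t(H), ties.method = "first")
      if (identical(a, assign_prev)) stable <- stable + 1L
      else { stable <- 0L; assign_prev <- a }
      if (stable >= stable_checks) break
    }
  }
  list(W = W, H = H, divergence = kl_divergence(V, W, H),
       assignment = max.col(t(H), ties.method = "first"), iterations = iter)
}

# Validate and prepare V: canonical labels when 96 rows, epsilon-floor
# all-zero rows so W keeps a full set of classes, drop all-zero samples.
.prepare_v <- function(V, rank) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  zero_col <- colSums(V) == 0
  if (any(zero_col)) {
    warning("dropping ", sum(zero_col), " all-zero sample(s): ",
            paste(colnames(V)[zero_col], collapse = ", "))
    V <- V[, !zero_col, drop = FALSE]
  }
  if (rank >= min(dim(V)))
    stop("rank must be smaller than both dimensions of V (",
         nrow(V), " x ", ncol(V), ")")
  zero_row <- rowSums(V) == 0
  if (any(zero_row))
    V[zero_row, ] <- 1e-10
  V
}

# Run n_runs seeded restarts; per-run seeds are seed + run index so results
# are reproducible and independent of scheduling.
.nmf_runs <- function(V, rank, n_runs, seed, ...) {
  lapply(seq_len(n_runs), function(i) .nmf_run(V, rank, seed + i, ...))
}

#' Extract mutational signatures by KL-NMF
#'
#' Factorizes a non-negative mutation matrix `V` (classes x samples) as
#' `V ~ W %*% H` using the Brunet multiplicative updates with the
#' generalized KL divergence, over `n_runs` random restarts; the run with
#' the lowest divergence is returned. Columns of `W` (the signatures) are
#' normalised to sum to 1, with `H` rescaled so `W %*% H` is unchanged.
#'
#' @param V Non-negative matrix (typically 96 x samples; see
#'   [mutation_matrix()]). All-zero samples are dropped with a warning;
#'   all-zero classes are floored at a tiny epsilon so signatures keep all
#'   96 rows.
#' @param rank Number of signatures `k` (must be `< min(dim(V))`).
#' @param n_runs Number of random restarts (default 200).
#' @param seed Integer seed; restart `i` uses `seed + i`.
#' @param max_iter Iteration cap per run (default 2000).
#' @param check_every,stable_checks Convergence: the per-sample
#'   dominant-signature assignment is checked every `check_every` iterations
#'   and the run stops after `stable_checks` consecutive unchanged checks.
#' @return An object of class `mutspec_nmf`: list with `W` (classes x k,
#'   columns sum to 1), `H` (k x samples), `divergence`, `rank`, `n_runs`,
#'   `seed`, `iterations`, `run_divergences`.
#' @export
factorize <- function(V, rank, n_runs = 200L, seed = 1L, max_iter = 2000L,
                      check_every = 10L, stable_checks = 40L) {
  V <- .prepare_v(V, rank)
  runs <- .nmf_runs(V, rank, n_runs, seed, max_iter = max_iter,
                    check_every = check_every, stable_checks = stable_checks)
  divs <- vapply(runs, `[[`, numeric(1), "divergence")
  best <- runs[[which.min(divs)]]
  s <- colSums(best$W)
  W <- sweep(best$W, 2L, s, "/")
  H <- best$H * s
  sig_names <- paste0("Sig", LETTERS[seq_len(rank)])
  dimnames(W) <- list(rownames(V), sig_names)
  dimnames(H) <- list(sig_names, colnames(V))
  structure(list(V = V, W = W, H = H, divergence = min(divs), rank = rank,
                 n_runs = n_runs, seed = seed, iterations = best$iterations,
                 run_divergences = divs),
            class = "mutspec_nmf")
}

#' @export
print.mutspec_nmf <- function(x, ...) {
  cat("KL-NMF factorization: rank", x$rank, "|", ncol(x$H), "samples |",
      x$n_runs, "restarts\n")
  cat("best divergence:", format(x$divergence), "\n")
  invisible(x)
}

#' Consensus matrix and cophenetic coefficient at a given rank
#'
#' Runs `n_runs` seeded NMF restarts; each run yields a binary connectivity
#' matrix (`C[i, j] = 1` iff samples i and j share the same dominant
#' signature). Their mean is the consensus matrix, whose entries measure
#' clustering stability. The cophenetic coefficient is the Pearson
#' correlation between the consensus dissimilarities (`1 - consensus`) and
#' the cophenetic distances of their average-linkage hierarchical
#' clustering; values near 1 indicate a stable factorization rank.
#'
#' @inheritParams factorize
#' @param n_runs Restarts used for the consensus (default 50).
#' @return A list with `consensus` (samples x samples, symmetric, unit
#'   diagonal) and `cophenetic` (`NA` when the consensus is degenerate,
#'   e.g. all samples always co-cluster).
#' @export
consensus_and_cophenetic <- function(V, rank, n_runs = 50L, seed = 1L, ...) {
  V <- .prepare_v(V, rank)
  runs <- .nmf_runs(V, rank, n_runs, seed, ...)
  m <- ncol(V)
  cons <- matrix(0, m, m)
  for (r in runs) {
    a <- r$assignment
    cons <- cons + outer(a, a, "==")
  }
  cons <- cons / n_runs
  dimnames(cons) <- list(colnames(V), colnames(V))
  d <- stats::as.dist(1 - cons)
  coph <- if (stats::sd(d) == 0) NA_real_ else {
    hc <- stats::hclust(d, method = "average")
    cd <- stats::cophenetic(hc)
    if (stats::sd(cd) == 0) NA_real_ else stats::cor(d, cd)
  }
  list(consensus = cons, cophenetic = coph, runs = runs)
}

#' Survey factorization ranks
#'
#' For each candidate rank, computes the cophenetic coefficient of the
#' consensus matrix and the residual sum of squares
#' `RSS = sum((V - W %*% H)^2)` of the lowest-divergence run; optionally the
#' same on a shuffled copy of `V` (all cells permuted: the value multiset is
#' preserved, the class/sample structure destroyed) as a null baseline. The
#' suggested rank is the last rank before the cophenetic coefficient first
#' decreases.
#'
#' @inheritParams factorize
#' @param ranks Candidate ranks (default `2:8`).
#' @param n_runs Restarts per rank (default 50).
#' @param shuffle Also survey a shuffled copy of `V` (default `TRUE`).
#' @return An object of class `rank_survey`: list with `table` (data.frame
#'   of `rank`, `cophenetic`, `rss` and shuffled counterparts) and
#'   `suggested_rank` (`NA` when the cophenetic never decreases).
#' @export
rank_survey <- function(V, ranks = 2:8, n_runs = 50L, seed = 1L,
                        shuffle = TRUE, ...) {
  V <- .prepare_v(V, max(ranks))
  survey_one <- function(M, seed_off) {
    t(vapply(ranks, function(k) {
      cc <- consensus_and_cophenetic(M, k, n_runs = n_runs,
                                     seed = seed + seed_off + 1000L * k, ...)
      divs <- vapply(cc$runs, `[[`, numeric(1), "divergence")
      best <- cc$runs[[which.min(divs)]]
      c(cophenetic = cc$cophenetic,
        rss = sum((M - best$W %*% best$H)^2))
    }, c(cophenetic = 0, rss = 0)))
  }
  obs <- survey_one(V, 0L)
  tab <- data.frame(rank = ranks, cophenetic = obs[, "cophenetic"],
                    rss = obs[, "rss"])
  if (shuffle) {
    set.seed(seed + 777L)
    Vs <- matrix(sample(as.vector(V)), nrow(V), ncol(V),
                 dimnames = dimnames(V))
    sh <- survey_one(Vs, 500000L)
    tab$cophenetic_shuffled <- sh[, "cophenetic"]
    tab$rss_shuffled <- sh[, "rss"]
  }
  suggested <- NA_integer_
  cp <- tab$cophenetic
  for (i in seq_along(ranks)[-1]) {
    if (!is.na(cp[i]) && !is.na(cp[i - 1]) && cp[i] < cp[i - 1]) {
      suggested <- ranks[i - 1]
      break
    }
  }
  structure(list(table = tab, suggested_rank = suggested, n_runs = n_runs,
                 seed = seed),
            class = "rank_survey")
}

#' @export
print.rank_survey <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("suggested rank:", x$suggested_rank, "\n")
  invisible(x)
}

#' Per-sample signature contributions and sample clusters
#'
#' Reports, per sample, the absolute contribution of each signature (the
#' rescaled rows of `H`), the proportional contributions (normalised to sum
#' to 1 per sample), and a cluster assignment from average-linkage
#' hierarchical clustering of the proportion vectors (Euclidean distance,
#' tree cut into `n_clusters`). A per-cluster summary gives the sample count
#' and the mean proportional contribution of each signature.
#'
#' @param fact A `mutspec_nmf` object from [factorize()].
#' @param n_clusters Number of clusters (default: the factorization rank).
#' @return An object of class `contribution_summary`: list with
#'   `per_sample` (data.frame) and `clusters` (data.frame).
#' @export
contributions_and_clusters <- function(fact, n_clusters = fact$rank) {
  stopifnot(inherits(fact, "mutspec_nmf"))
  H <- fact$H
  m <- ncol(H)
  if (m < n_clusters)
    stop("cannot form ", n_clusters, " clusters from ", m, " samples")
  tot <- colSums(H)
  prop <- sweep(H, 2L, tot, "/")
  cl <- if (m == 1L) 1L else {
    hc <- stats::hclust(stats::dist(t(prop)), method = "average")
    stats::cutree(hc, k = n_clusters)
  }
  per_sample <- data.frame(sample_id = colnames(H), total = tot,
                           t(H), t(prop) |>
                             `colnames<-`(paste0("prop_", rownames(H))),
                           cluster = as.integer(cl),
                           check.names = FALSE, row.names = NULL)
  agg <- stats::aggregate(t(prop), by = list(cluster = as.integer(cl)), mean)
  clusters <- data.frame(cluster = agg$cluster,
                         n_samples = as.integer(table(cl)[as.character(agg$cluster)]),
                         agg[, -1, drop = FALSE], check.names = FALSE,
                         row.names = NULL)
  structure(list(per_sample = per_sample, clusters = clusters),
            class = "contribution_summary")
}

#' @export
print.contribution_summary <- function(x, ...) {
  cat("Signature contributions for", nrow(x$per_sample), "samples in",
      nrow(x$clusters), "cluster(s)\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}
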