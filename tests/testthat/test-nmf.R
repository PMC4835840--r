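test_that("KL divergence is non-increasing across multiplicative updates", {
  set.seed(11)
  for (case in 1:5) {
    V <- matrix(runif(10 * 6, 0.1, 5), 10, 6)
    W <- matrix(runif(10 * 2), 10, 2)
    H <- matrix(runif(2 * 6), 2, 6)
    d_prev <- kl_divergence(V, W, H)
    for (i in 1:100) {
      up <- kl_update(V, W, H)
      W <- up$W; H <- up$H
      d <- kl_divergence(V, W, H)
      expect_lte(d, d_prev + 1e-9)
      d_prev <- d
    }
  }
})

test_that("an exact factorization is a fixed point with zero divergence", {
  set.seed(3)
  W0 <- matrix(runif(8 * 2, 0.5, 2), 8, 2)
  H0 <- matrix(runif(2 * 5, 0.5, 2), 2, 5)
  V <- W0 %*% H0
  expect_equal(kl_divergence(V, W0, H0), 0)
  up <- kl_update(V, W0, H0)
  expect_equal(up$W, W0, tolerance = 1e-8)
  expect_equal(up$H, H0, tolerance = 1e-8)
})

test_that("rank-1 structure is recovered up to reciprocal scaling", {
  set.seed(4)
  w <- runif(12, 0.2, 2); h <- runif(6, 0.2, 2)
  V <- outer(w, h)
  f <- factorize(V, rank = 1, n_runs = 3, seed = 9)
  expect_equal(unname(f$W[, 1]), w / sum(w), tolerance = 1e-6)
  expect_equal(unname(f$W %*% f$H), unname(V), tolerance = 1e-6)
})

test_that("factorize normalizes W columns and preserves the product", {
  sim <- simulate_catalog(n_signatures = 2, n_samples = 8,
                          mutations_per_sample = 300, seed = 21)
  runs <- mutspectra:::.nmf_runs(mutspectra:::.prepare_v(sim$V, 2), 2, 3, 50)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "divergence"))]]
  f <- factorize(sim$V, rank = 2, n_runs = 3, seed = 50)
  expect_equal(unname(colSums(f$W)), c(1, 1))
  expect_equal(unname(f$W %*% f$H), unname(best$W %*% best$H),
               tolerance = 1e-9)
  expect_equal(rownames(f$W), sbs96_classes())
})

test_that("invalid ranks and degenerate samples are handled", {
  sim <- simulate_catalog(n_signatures = 2, n_samples = 5,
                          mutations_per_sample = 200, seed = 31)
  expect_error(factorize(sim$V, rank = 6, n_runs = 1, seed = 1), "rank")
  V <- sim$V
  V[, 3] <- 0
  expect_warning(f <- factorize(V, rank = 2, n_runs = 2, seed = 1),
                 "all-zero")
  expect_equal(ncol(f$H), 4L)
})

test_that("well-separated signatures are recovered from exact data", {
  sim <- simulate_catalog(n_signatures = 3, n_samples = 30,
                          mutations_per_sample = 1000, noise = "none",
                          seed = 41)
  f <- factorize(sim$V, rank = 3, n_runs = 10, seed = 42)
  cmp <- compare_signatures(f$W, sim$W)
  # greedy maximum-cosine matching: each true signature found
  expect_true(all(apply(cmp$similarity, 2, max) >= 0.99))
})

test_that("consensus matrices are symmetric, unit-diagonal and in [0,1]", {
  sim <- simulate_catalog(n_signatures = 3, n_samples = 12,
                          mutations_per_sample = 500, seed = 51)
  cc <- consensus_and_cophenetic(sim$V, rank = 3, n_runs = 10, seed = 52)
  C <- cc$consensus
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, ncol(C)))
  expect_true(all(C >= 0 & C <= 1))
  # stable clustering gives a cophenetic coefficient near 1
  expect_gt(cc$cophenetic, 0.95)
})

test_that("a degenerate consensus yields NA cophenetic", {
  # rank 1: every sample always assigned to the single signature
  sim <- simulate_catalog(n_signatures = 2, n_samples = 6,
                          mutations_per_sample = 200, seed = 61)
  cc <- consensus_and_cophenetic(sim$V, rank = 1, n_runs = 4, seed = 62)
  expect_true(all(cc$consensus == 1))
  expect_true(is.na(cc$cophenetic))
})

test_that("the rank survey recovers the true rank and orders RSS", {
  sim <- simulate_catalog(n_signatures = 3, n_samples = 30,
                          mutations_per_sample = 1000, seed = 14)
  sv <- rank_survey(sim$V, ranks = 2:5, n_runs = 20, seed = 16)
  expect_equal(sv$suggested_rank, 3L)
  # RSS decreases with rank (best-run fits; stochastic slack)
  rss <- sv$table$rss
  expect_true(all(diff(rss) <= 0.05 * rss[-length(rss)]))
  # randomization destroys structure: shuffled cophenetic below observed
  i3 <- which(sv$table$rank == 3)
  expect_lt(sv$table$cophenetic_shuffled[i3], sv$table$cophenetic[i3])
})

test_that("contributions are normalized and clusters match archetypes", {
  # archetypal samples, each pure in one of three signatures
  W <- simulate_signatures(3, seed = 81)
  H <- kronecker(diag(3), matrix(100, 1, 2))  # two pure samples per signature
  V <- round(W %*% H)
  colnames(V) <- paste0("P", 1:6)
  rownames(V) <- sbs96_classes()
  f <- factorize(V, rank = 3, n_runs = 10, seed = 82)
  cs <- contributions_and_clusters(f, n_clusters = 3)
  expect_equal(sort(unique(cs$per_sample$cluster)), 1:3)
  expect_equal(cs$clusters$n_samples, rep(2L, 3))
  prop_cols <- grep("^prop_", names(cs$per_sample))
  expect_equal(unname(rowSums(cs$per_sample[, prop_cols])), rep(1, 6))
  # every archetype is assigned almost entirely to one signature
  expect_true(all(apply(cs$per_sample[, prop_cols], 1, max) > 0.99))
  expect_error(contributions_and_clusters(f, n_clusters = 7), "clusters")
})

test_that("factorization is deterministic given the seed", {
  sim <- simulate_catalog(n_signatures = 2, n_samples = 8,
                          mutations_per_sample = 300, seed = 91)
  f1 <- factorize(sim$V, rank = 2, n_runs = 3, seed = 7)
  f2 <- factorize(sim$V, rank = 2, n_runs = 3, seed = 7)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
})
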