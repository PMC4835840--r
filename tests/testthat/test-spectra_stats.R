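test_that("count_spectra tallies classes, types and samples", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AAGCAGCAGCAA"))
  # three G>T SBS in plus-strand AGC context (-> G[C>A]T) and one deletion
  x <- cohort(chrom = rep("chr1", 4), pos = c(3L, 6L, 9L, 2L),
              ref = c("G", "G", "G", "A"), alt = c("T", "T", "T", "-"),
              sample_id = rep("S1", 4))
  ann <- annotate_cohort(x, g)
  cs <- count_spectra(ann)
  expect_equal(unname(cs$matrix96["G[C>A]T", "S1"]), 3L)
  expect_equal(sum(cs$matrix96), 3L)
  expect_equal(unname(cs$type_distribution[, "S1"]),
               unname(c(DEL = 1L, SNP = 3L)[rownames(cs$type_distribution)]))
  # conservation: 6-type counts equal 96-type counts within blocks
  expect_equal(unname(cs$sbs6["C>A", "S1"]), 3L)
  block <- function(s) sum(cs$matrix96[grepl(s, rownames(cs$matrix96),
                                             fixed = TRUE), "S1"])
  expect_equal(vapply(sbs6_types(), block, numeric(1)),
               stats::setNames(as.numeric(cs$sbs6[, "S1"]), sbs6_types()))
})

test_that("column sums equal per-sample classifiable SBS counts", {
  sim <- simulate_variants(
    target_profile = c("G[C>A]T" = 1, "A[C>T]G" = 2), n_variants = 3,
    seed = 7, sample_id = "S1")
  sim2 <- simulate_variants(
    target_profile = c("T[T>G]C" = 1, "C[C>G]G" = 1), n_variants = 2,
    seed = 8, sample_id = "S2")
  x <- rbind(as.data.frame(annotate_cohort(sim$variants, sim$genome)),
             as.data.frame(annotate_cohort(sim2$variants, sim2$genome)))
  cs <- count_spectra(validate_cohort(x))
  expect_equal(unname(colSums(cs$matrix96)), c(3, 2))
  # empty cohort: all-zero matrix with no samples
  ann0 <- annotate_cohort(cohort(), toy_genome())
  expect_equal(dim(count_spectra(ann0)$matrix96), c(96L, 0L))
})

test_that("annotation-column summaries are emitted when present", {
  x <- stranded_cohort(2, 1)
  x$Impact <- c("missense", "missense", "silent")
  cs <- count_spectra(x, annotation_column = "Impact")
  expect_equal(unname(cs$annotation_summary[, "S1"]), c(2L, 1L))
  expect_message(count_spectra(x, annotation_column = "nope"), "skipped")
})

test_that("strand-bias chi-squared matches the closed form", {
  r <- strand_bias_test(30, 10)
  expect_equal(r$chi2, 10)
  expect_equal(r$p, 1.565402e-3, tolerance = 1e-6)
  # independent oracle: stats::chisq.test goodness-of-fit
  ora <- stats::chisq.test(c(30, 10), p = c(0.5, 0.5))
  expect_equal(r$chi2, unname(ora$statistic))
  expect_equal(r$p, unname(ora$p.value))
  # symmetric counts: no bias
  r2 <- strand_bias_test(20, 20)
  expect_equal(r2$chi2, 0)
  expect_equal(r2$p, 1)
  # zero totals are skipped as NA
  r3 <- strand_bias_test(c(5, 0), c(5, 0))
  expect_true(is.na(r3$chi2[2]) && is.na(r3$p[2]) && is.na(r3$q[2]))
})

test_that("BH adjustment follows the step-up procedure", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
  # brute-force step-up oracle
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n); out[o] <- pmin(adj, 1); out
  }
  r <- strand_bias_test(rep(1, 6), rep(1, 6))
  expect_equal(bh_oracle(p), rep(0.06, 6))
  expect_equal(stats::p.adjust(p, "BH"), rep(0.06, 6))
  # q-values are monotone in the ordering of raw p-values
  set.seed(1)
  praw <- runif(20)
  q <- stats::p.adjust(praw, "BH")
  expect_true(all(diff(q[order(praw)]) >= -1e-12))
  expect_equal(q, bh_oracle(praw))
})

test_that("strand_bias splits counts by pyrimidine vs transcript strand", {
  x <- stranded_cohort(30, 10, sbs6 = "C>A")
  sb <- strand_bias(x, level = "6")
  row <- sb[sb$type == "C>A", ]
  expect_equal(row$n_nontranscribed, 30L)
  expect_equal(row$n_transcribed, 10L)
  expect_equal(row$chi2, 10)
  expect_equal(row$p, 1.565402e-3, tolerance = 1e-6)
  expect_true(all(is.na(sb$chi2[sb$type != "C>A"])))
  # ambiguous/unknown strands are excluded from the stranded analysis
  x$strand[1] <- "ambiguous"
  sb2 <- strand_bias(x, level = "6")
  expect_equal(sb2$n_nontranscribed[sb2$type == "C>A"], 29L)
  # the 96-class level tests the same counts at context resolution
  sb96 <- strand_bias(x, level = "96")
  expect_equal(sb96$n_nontranscribed[sb96$type == "A[C>A]A"], 29L)
  expect_equal(nrow(sb96), 96L)
})

test_that("chromosomal distribution computes Pearson correlation", {
  mk <- function(counts) {
    chroms <- paste0("chr", seq_along(counts))
    x <- cohort(chrom = rep(chroms, counts),
                pos = rep(1L, sum(counts)) + seq_len(sum(counts)),
                ref = "C", alt = "A", sample_id = "S1")
    x$sbs6 <- "C>A"
    x
  }
  lens <- c(chr1 = 3, chr2 = 2, chr3 = 1)
  expect_equal(chrom_distribution(mk(c(3, 2, 1)), lens * 100)$r, 1.0)
  expect_equal(chrom_distribution(mk(c(1, 2, 3)), lens)$r, -1.0)
  expect_equal(chrom_distribution(mk(c(1, 2, 4)),
                                  c(chr1 = 1, chr2 = 2, chr3 = 3))$r,
               0.9819805, tolerance = 1e-6)
  # fewer than 3 chromosomes: NA
  expect_true(is.na(chrom_distribution(mk(c(1, 2)),
                                       c(chr1 = 1, chr2 = 2))$r))
})

test_that("pooling sums rows, preserves totals and is idempotent", {
  m <- mutation_matrix(matrix(rpois(192, 3), 96, 2),
                       samples = c("S1", "S2"))
  pool <- pool_samples(m)
  expect_equal(colnames(pool), "Pool")
  expect_equal(unname(pool[, 1]), unname(rowSums(m)))
  expect_equal(sum(pool), sum(m))
  expect_equal(pool_samples(pool), pool)
  # single sample pools to itself
  single <- m[, 1, drop = FALSE]
  expect_equal(unname(pool_samples(single)[, 1]), unname(single[, 1]))
})
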