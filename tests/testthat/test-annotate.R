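test_that("fetch_context returns centred, N-padded windows", {
  g <- toy_genome()
  expect_equal(fetch_context(g, "chr1", 3), "CGT")
  expect_equal(fetch_context(g, "chr1", 1), "NAC")
  expect_equal(fetch_context(g, "chr1", 5), "TAN")
  expect_equal(fetch_context(g, "chr1", 3, flank = 2), "ACGTA")
  expect_equal(fetch_context(g, "chr1", 1, flank = 3), "NNNACGT")
  expect_equal(nchar(fetch_context(g, "chr2", 4, flank = 3)), 7L)
  expect_error(fetch_context(g, "chr9", 1), "contig")
  expect_error(fetch_context(g, "chr1", 9), "outside")
  # chromosome label normalization against the genome's contig names
  expect_equal(fetch_context(g, "1", 3), "CGT")
})

test_that("classify_sbs applies pyrimidine normalization", {
  expect_equal(classify_sbs("G", "T", "AGC"),
               data.frame(sbs6 = "C>A", context = "GCT",
                          class96 = "G[C>A]T"))
  expect_equal(classify_sbs("C", "T", "ACG"),
               data.frame(sbs6 = "C>T", context = "ACG",
                          class96 = "A[C>T]G"))
  expect_error(classify_sbs("C", "C", "ACG"), "differ")
  expect_error(classify_sbs("C", "T", "ATG"), "genome build")
  # N at a flank: 96-class NA, 6-type kept
  out <- classify_sbs("C", "T", "NCG")
  expect_true(is.na(out$class96))
  expect_equal(out$sbs6, "C>T")
})

test_that("the image of classify_sbs is exactly the 96 classes and 6 types", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = bases, alt = bases, up = bases, down = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  out <- classify_sbs(grid$ref, grid$alt,
                      paste0(grid$up, grid$ref, grid$down))
  expect_equal(nrow(out), 12 * 16)
  expect_setequal(unique(out$class96), sbs96_classes())
  expect_length(unique(out$class96), 96L)
  expect_setequal(unique(out$sbs6), sbs6_types())
})

test_that("classify_sbs is invariant under reverse complement", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:1000) {
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    ctx <- paste0(sample(bases, 1), ref, sample(bases, 1))
    a <- classify_sbs(ref, alt, ctx)
    b <- classify_sbs(chartr("ACGT", "TGCA", ref),
                      chartr("ACGT", "TGCA", alt),
                      reverse_complement(ctx))
    expect_identical(a, b)
  }
})

test_that("assign_strand reports agreement, ambiguity and intergenic status", {
  tx <- toy_transcripts()
  x <- cohort(chrom = rep("chr1", 4), pos = c(120L, 170L, 250L, 500L),
              ref = rep("C", 4), alt = rep("A", 4),
              sample_id = rep("S1", 4))
  expect_equal(assign_strand(x, tx),
               c("+", "ambiguous", "-", "unknown"))
  y <- cohort(chrom = "chr2", pos = 5L, ref = "C", alt = "T",
              sample_id = "S1")
  expect_equal(assign_strand(y, tx), "unknown")
})

test_that("annotate_cohort composes context, strand and class", {
  g <- toy_genome()
  x <- cohort(chrom = "chr1", pos = 3L, ref = "G", alt = "T",
              sample_id = "S1")
  ann <- annotate_cohort(x, g)
  expect_equal(ann$context, "CGT")
  expect_equal(ann$strand, "unknown")
  # pyrimidine normalization: rc("CGT") = "ACG", so G>T becomes A[C>A]G
  expect_equal(ann$class96, "A[C>A]G")
  expect_equal(ann$sbs6, "C>A")
  expect_identical(classify_sbs("G", "T", "CGT")$class96, "A[C>A]G")

  # ref mismatching the genome: left unclassified, with a warning
  x2 <- cohort(chrom = c("chr1", "chr1"), pos = c(3L, 4L),
               ref = c("G", "A"), alt = c("T", "C"),
               sample_id = c("S1", "S1"))
  expect_warning(ann2 <- annotate_cohort(x2, g), "does not match")
  expect_equal(ann2$class96, c("A[C>A]G", NA))

  # non-SBS get a type but no class; empty cohorts pass through
  x3 <- cohort(chrom = "chr2", pos = 2L, ref = "TA", alt = "-",
               sample_id = "S1")
  ann3 <- annotate_cohort(x3, g)
  expect_equal(ann3$variant_type, "DEL")
  expect_true(is.na(ann3$class96))
  expect_equal(nrow(annotate_cohort(cohort(), g)), 0L)
})

test_that("transcript tables load from BED and refGene formats", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\ttxA\t0\t+",
               "chr1\t149\t260\ttxB\t0\t-"), bed)
  tx <- read_transcripts(bed)
  expect_s4_class(tx, "GRanges")
  expect_equal(GenomicRanges::start(tx), c(100L, 150L))
  expect_equal(as.character(GenomicRanges::strand(tx)), c("+", "-"))

  rg <- tempfile(fileext = ".txt")
  writeLines(c("name\tchrom\tstrand\ttxStart\ttxEnd",
               "txA\tchr1\t+\t99\t200"), rg)
  tx2 <- read_transcripts(rg)
  expect_equal(GenomicRanges::start(tx2), 100L)
  expect_equal(GenomicRanges::end(tx2), 200L)
})
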