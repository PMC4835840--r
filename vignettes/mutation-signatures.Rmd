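---
title: "Mutation spectra and signature extraction: models and design notes"
author: "mutspectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation spectra and signature extraction: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutspectra)
```

## The scientific problem

Somatic mutations accumulate in tumor genomes under the combined action of
mutagenic exposures (tobacco, UV, aflatoxin, ...), endogenous processes
(spontaneous deamination at CpG sites, APOBEC editing) and DNA-repair
deficiencies. Each process leaves a characteristic imprint on *which*
substitutions occur and in *which* local sequence context. Summarising a
tumor's single-base substitutions (SBS) over the 96 canonical classes —
six pyrimidine-normalized substitution types × 16 flanking-base
combinations — and decomposing a cohort's 96 × samples count matrix into a
small number of non-negative "signatures" is the standard route from raw
variant calls to hypotheses about etiology.

This vignette documents the models, conventions and numerical choices the
package makes, and what its synthetic benchmarks do and do not demonstrate.

## Mutation classes and pyrimidine normalization

DNA is double-stranded: a G→T change on the sequenced (plus) strand is the
same molecular event as C→A on the opposite strand. Classes are therefore
reported with respect to the strand carrying the pyrimidine (C or T)
reference base; when the stated reference base is a purine, the alleles and
the trinucleotide context are reverse-complemented first. This yields
exactly 6 substitution types and 96 context classes; `classify_sbs()` is
invariant under simultaneous reverse complement of its inputs, and the
canonical row ordering (`sbs96_classes()`: C>A, C>G, C>T, T>A, T>C, T>G
blocks, contexts ordered A/C/G/T by upstream then downstream base) is fixed
so that all outputs are byte-comparable across runs and compatible with
standard 96-row reference matrices.

Contexts are retrieved from the reference FASTA with a configurable flank
(default 1, i.e. the trinucleotide); positions beyond contig ends are
N-padded. An `N` anywhere in the context makes the 96-class undefined while
the 6-type is still counted — a deliberate minimal-data-loss rule. A stated
reference allele that disagrees with the genome is a consistency error
(usually a genome-build mix-up); such variants are left unclassified and
counted in a warning rather than silently dropped or mis-assigned.

## Strand assignment and strand bias

Transcription-coupled repair and transcription-associated damage make
mutation counts differ between the template (transcribed) and coding
(non-transcribed) strands of genes. Strand is assigned from a flat stranded
interval table (BED-6 or refGene-style); exon structure is not needed
because only the orientation is consumed. When transcripts on both strands
overlap a position the variant is labelled `ambiguous` and excluded from
stranded analyses (but kept everywhere else) — overlapping antisense genes
give no usable orientation. Variants outside any transcript are `unknown`.

The counting convention: a mutation sits on the **non-transcribed** strand
when the strand carrying the pyrimidine of the mutated pair equals the
transcript's strand. This is the convention used by stranded mutation
catalogs; other choices merely swap the two labels.

Per type, the test is a one-sample chi-squared goodness-of-fit against a
50/50 expectation with 1 degree of freedom and no continuity correction:
`chi2 = (a − b)² / (a + b)`. Types with zero totals are reported `NA` and
excluded from the multiple-testing family. Benjamini–Hochberg correction is
applied per analysis level (across the 6 types, or across the tested 96
classes), since each level constitutes one family of simultaneous tests.
Both levels are offered.

## Filtering

Somatic call sets are contaminated by germline polymorphisms and by
unreliable calls in segmental duplications. A variant is removed when it
exactly matches (chrom, pos, ref, alt) an entry of an allele-identity
database without frequencies (a dbSNP-style list: any match removes), when
it matches an entry with population frequency above `max_freq` in a
frequency-bearing database, or when its position falls in an excluded
region. The default `max_freq = 0.01` reflects the usual "common in human
populations (> 1 %)" cut-off; position-only matching is available behind a
flag for lists that lack alleles. Filtering is idempotent and always
partitions the input into kept + removed, with per-criterion counts.

## KL-NMF signature extraction

The count matrix V (96 × S) is factorized as V ≈ W·H with W, H ≥ 0 by the
Brunet multiplicative updates for the generalized Kullback–Leibler
divergence; the KL objective is the natural choice for count data (it is
the Poisson log-likelihood up to a constant). Raw counts are used — no
frequency conversion and no trinucleotide-opportunity normalization — so
extracted signatures live on the same scale as standard reference
catalogs.

Numerical choices:

* **Initialization**: W and H entries are drawn uniform(0, 1] scaled by
  `mean(V)`. Multiplicative updates rescale within a few iterations, so
  only the support randomization matters; each restart uses seed
  `seed + run index`, making results reproducible and independent of any
  scheduling.
* **Update order**: H first, then W with the updated H; denominators are
  floored at machine epsilon. The divergence is non-increasing along the
  update path (a property the test suite checks numerically with 1e-9
  slack over thousands of steps).
* **Convergence**: Brunet's connectivity-stability criterion — every 10
  iterations each sample's dominant signature is recorded; a run stops
  after 40 consecutive unchanged checks, capped at 2000 iterations. This
  targets the quantity the consensus analysis consumes rather than a raw
  objective tolerance.
* **Restarts**: 200 by default for a final factorization, 50 per rank for
  surveys; the lowest-divergence run wins. W columns are then normalized
  to sum to 1 with H rescaled so W·H is unchanged.
* **Degenerate input**: all-zero samples are dropped with a warning
  (they carry no information and break the updates); all-zero classes are
  floored at 1e-10 instead of dropped so W always keeps 96 rows and stays
  comparable to reference matrices.

## Rank estimation by consensus clustering

NMF requires the rank k up front. For each candidate rank, every restart
yields a binary connectivity matrix over samples (1 iff two samples share a
dominant signature); the mean over restarts is the consensus matrix, and
the cophenetic coefficient — the correlation between consensus
dissimilarities and the cophenetic distances of their average-linkage
dendrogram — measures how stable the sample clustering is at that rank.
The survey reports cophenetic and best-run RSS per rank, on the observed
matrix and on a shuffled copy (all cells globally permuted: the value
multiset is preserved, all class/sample structure destroyed) as a null
baseline. The suggested rank is the last rank before the cophenetic
coefficient first decreases. A consensus with zero variance (e.g. at rank
1, or when all samples always co-cluster) has no defined cophenetic
coefficient and is reported `NA`.

This "first decrease" rule is simple and standard, but it is worth knowing
its failure mode: when a cohort contains samples genuinely balanced between
two processes, their dominant assignment flips between restarts, depressing
the cophenetic coefficient at the true rank while the rank-2 merge (or a
higher-rank split) stays artificially stable. On such data the curve should
be inspected, not just the single suggested value — which is why the full
table is always returned and written.

## Contributions and sample clustering

Per sample, absolute contributions are the columns of the rescaled H and
proportions are normalized per sample. Samples are clustered by
average-linkage hierarchical clustering of the *proportion* vectors
(Euclidean distance), cut into k clusters by default; proportions rather
than absolute loads are used so that hypermutated samples cluster by
process composition, not by burden. The cluster summary reports sample
counts and mean proportional contributions.

## Cosine comparison with reference signatures

Extracted signatures are compared to any user-supplied 96-row reference
matrix by cosine similarity after both matrices are reordered to the
canonical class order (so any complete row permutation is accepted; a
missing or unrecognised label is an error listing the offenders). For
non-negative profiles the cosine lies in [0, 1]; matches are flagged
strictly above the threshold (default 0.9). No refitting or signature
attribution is performed — this is a comparison, not a decomposition.

## The synthetic-data generator

The generator exists so every stage is testable offline, and its defaults
define the package's benchmark conditions:

* **Signatures**: Dirichlet-distributed profiles with gamma shape 0.1 —
  sparse, as real signatures are — rejection-sampled until every pair is at
  cosine distance ≥ 0.8. This strong separation, together with
  single-process-dominated exposures (Dirichlet concentration 0.1), defines
  "well-separated": each sample has a clear dominant process, so the
  consensus at the true rank is stable and rank recovery is identifiable.
  With milder settings (concentration ≥ 0.2, separation 0.6) a noticeable
  fraction of simulated cohorts contains balanced samples and the rank
  survey exhibits exactly the failure mode described above — a property of
  the selection rule on ambiguous cohorts, not a defect of the updates.
* **Catalogs**: 30 samples × ~1000 mutations by default; per-sample
  multinomial sampling (count-preserving) by default, per-cell Poisson for
  robustness checks, or noise-free rounding.
* **Variant lists**: a uniform-composition random contig plus variants
  placed only at positions whose plus-strand trinucleotide (or its reverse
  complement) matches the drawn class, with integer class counts from
  largest-remainder apportionment — so annotation + counting reproduces the
  target spectrum *exactly*, giving a closed-loop oracle for the whole
  annotate/count path.

What passing these benchmarks does **not** show: real genomes have biased
base composition, CpG depletion, clustered mutations (kataegis),
replication-timing and expression covariates, and signatures far less
separated than cosine distance 0.8 (e.g. the tobacco-chewing/aflatoxin
pair of the COSMIC catalog). Recovery quality on real cohorts degrades
with signature similarity, flat exposures and small mutation counts; the
benchmarks here validate correctness of the machinery, not power on hard
cohorts.

## Problem sizes used by the test suite

The shipped tests run the recovery benchmark at 3 signatures × 30 samples ×
1000 mutations with 20 restarts (and 20 restarts per surveyed rank over
2–6), and smaller configurations elsewhere; these sizes exhibit the
documented behaviour stably across seeds while keeping the default test run
short. The same conditions are what `scripts/acceptance.R` recomputes.

## Known limitations

* VCF input uses only CHROM/POS/REF/ALT (+ ID/FILTER pass-through);
  genotype columns and INFO annotations other than AF (for polymorphism
  databases) are ignored.
* Strand assignment uses whole-transcript intervals; a variant in an
  intron still counts as transcribed, and UTR/exon distinctions are out of
  scope.
* No indel or doublet signatures: classes are SBS-only, by design, to stay
  comparable with the standard 96-class catalogs.
* The NMF is the plain Brunet scheme; no bootstrap-and-cluster pipeline,
  no sparsity penalties, and no zeroing of low counts — appropriate for
  small-to-medium cohorts, not a re-implementation of large-scale
  discovery frameworks.
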