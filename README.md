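# mutspectra

Analysis of somatic mutation spectra and mutational signatures in cancer
genomes, for researchers who have a list of somatic variant calls (from
whole-genome, whole-exome or targeted sequencing of human or mouse tumors,
or from experimental mutagenesis systems) and want to know which mutational
processes shaped them.

The package covers the classic somatic-spectrum workflow end to end:

1. **Read** variant tables — VCF 4.1 or tab-delimited dialects (generic,
   ICGC, TCGA, COSMIC headers) — and split multi-sample files by sample ID.
2. **Annotate** each single-base substitution (SBS) with its trinucleotide
   sequence context from a reference FASTA and its transcript strand from a
   stranded interval table, then classify it into the pyrimidine-normalized
   6-type (C>A, C>G, C>T, T>A, T>C, T>G) and 96-type (context) classes.
3. **Filter** likely germline polymorphisms (exact chrom/pos/ref/alt matches
   against dbSNP-style lists, or frequency-thresholded matches against
   1000-genomes/ESP-style lists) and variants in segmental-duplication
   regions.
4. **Summarise** spectra: 96 × samples mutation count matrices,
   transcriptional strand bias (chi-squared goodness-of-fit per type,
   Benjamini–Hochberg corrected), per-chromosome counts with a Pearson
   correlation against chromosome length, and pooled-sample statistics.
5. **Extract signatures** by non-negative matrix factorization: the Brunet
   multiplicative updates minimising the generalized Kullback–Leibler
   divergence

   D(V‖WH) = Σᵢⱼ ( Vᵢⱼ · log(Vᵢⱼ/(WH)ᵢⱼ) − Vᵢⱼ + (WH)ᵢⱼ ),

   where V is the 96 × S count matrix, W holds the signature profiles
   (columns sum to 1) and H the per-sample contributions. The factorization
   rank is estimated by consensus clustering over random restarts: the
   cophenetic coefficient of the consensus matrix is tracked across
   candidate ranks (2–8 by default, 50 restarts each) together with the
   residual sum of squares, on the observed and on shuffled data.
6. **Compare** extracted signatures against any reference signature matrix
   (e.g. the COSMIC catalog in its standard 96-row TSV layout) by cosine
   similarity; values above 0.9 are conventionally a good match.

A synthetic-data module generates toy genomes, variant lists realizing an
exact target spectrum, and mutation catalogs sampled from known signature
mixtures, so the whole pipeline is testable without any download.

## Worked example

Simulate a 30-sample catalog drawn from 3 well-separated signatures
(~1000 mutations per sample), recover the signatures, estimate the rank and
match against the ground truth:

```r
library(mutspectra)

sim  <- simulate_catalog(n_signatures = 3, n_samples = 30,
                         mutations_per_sample = 1000, seed = 1)
fact <- factorize(sim$V, rank = 3, n_runs = 20, seed = 2)
fact
#> KL-NMF factorization: rank 3 | 30 samples | 20 restarts
#> best divergence: 895.2069

compare_signatures(fact, sim$W)
#> Cosine similarity (threshold 0.9):
#>      TrueSigA TrueSigB TrueSigC
#> SigA    1.000    0.057    0.076
#> SigB    0.061    0.999    0.050
#> SigC    0.081    0.052    0.999
#> SigA -> TrueSigA
#> SigB -> TrueSigB
#> SigC -> TrueSigC

rank_survey(sim$V, ranks = 2:5, n_runs = 20, seed = 3)
#>  rank cophenetic       rss cophenetic_shuffled rss_shuffled
#>     2  0.9736406 381500.16           0.6994602      1842736
#>     3  0.9897175  24095.07           0.8154750      1706110
#>     4  0.9834130  22091.19           0.7664312      1567896
#>     5  0.9674456  21126.88           0.7722367      1479701
#> suggested rank: 3
```

Each extracted signature matches exactly one ground-truth signature at
cosine ≥ 0.999, the cophenetic coefficient peaks at the true rank 3 (and is
far lower on shuffled data), and the RSS curve has its inflection there.
Per-sample contributions and sample clusters:

```r
contributions_and_clusters(fact)
#> Signature contributions for 30 samples in 3 cluster(s)
#>  cluster n_samples       SigA       SigB       SigC
#>        1         5 0.04363295 0.93618417 0.02018288
#>        2        15 0.87312396 0.06003183 0.06684421
#>        3        10 0.12839650 0.08154004 0.79006345
```

Strand bias uses a 1-df chi-squared goodness-of-fit against equal counts on
the transcribed and non-transcribed strands; for counts (30, 10):

```r
strand_bias_test(30, 10)
#> chi2: 10   p: 0.001565402
```

The same steps run from the shell via the thin CLI wrapper
(`inst/cli/mutspectra.R`) with subcommands `run`, `annot`, `filter`,
`split`, `stat`, `nmf`, `compare` and `simulate`, or as one configured
pipeline with `run_pipeline()`, which writes TSV outputs plus a
`manifest.json` recording seeds, parameters and per-stage record counts.
Identically seeded runs are byte-identical.

## Scope notes

The package consumes pre-existing functional annotation columns (passing
them through and summarising them) rather than running an annotator itself;
it bundles no polymorphism or reference-signature databases — these are
user-supplied files, with synthetic stand-ins generated for tests.
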