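Package: mutspectra
Title: Mutation Spectrum Statistics and Signature Extraction for Somatic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the analysis of somatic single-base substitution (SBS)
    spectra in cancer genomes: reading variant tables (VCF 4.1 and common
    tab-delimited dialects), annotating variants with trinucleotide sequence
    context and transcript strand from a reference FASTA and a transcript
    interval table, filtering against polymorphism lists and
    segmental-duplication regions, computing mutation-spectrum statistics
    (6-type and 96-type distributions, transcriptional strand bias with
    chi-squared tests and Benjamini-Hochberg correction, per-chromosome
    correlation with chromosome size), extracting mutational signatures by
    Kullback-Leibler non-negative matrix factorization with consensus-based
    factorization-rank estimation, and matching extracted signatures against
    reference signature matrices by cosine similarity. A synthetic-data
    module generates toy genomes, variant lists and mutation catalogs from
    known signature mixtures so the whole pipeline is testable offline.
License: GPL (>= 2)
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
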