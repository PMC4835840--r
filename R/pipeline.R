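#' Build a pipeline run configuration
#'
#' Collects and validates the parameters of a full analysis run. Every
#' field has a CLI-flag counterpart and the whole configuration round-trips
#' through a YAML file ([read_run_config()]).
#'
#' @param input Path to a variant file (VCF or tab-delimited).
#' @param genome Path to the reference FASTA.
#' @param transcripts Optional transcripts BED/refGene path (strand
#'   assignment is skipped without it).
#' @param outdir Output directory.
#' @param flank Context half-width (default 1).
#' @param dbs Optional named character vector of polymorphism-db paths.
#' @param segdup Optional BED of excluded regions.
#' @param max_freq Polymorphism frequency threshold (default 0.01).
#' @param rank Factorization rank for signature extraction; `NULL` to take
#'   the rank suggested by the survey.
#' @param rank_min,rank_max Survey range (default 2..8).
#' @param n_runs NMF restarts for the final factorization (default 200).
#' @param survey_runs NMF restarts per surveyed rank (default 50).
#' @param seed Integer seed (default 1).
#' @param reference Optional reference signature matrix TSV for the
#'   comparison stage.
#' @param threshold Cosine match threshold (default 0.9).
#' @param stages Character vector of stages to run, a subset of
#'   `c("annot", "filter", "split", "stat", "nmf", "compare")`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input, genome, transcripts = NULL, outdir,
                       flank = 1L, dbs = NULL, segdup = NULL,
                       max_freq = 0.01, rank = NULL, rank_min = 2L,
                       rank_max = 8L, n_runs = 200L, survey_runs = 50L,
                       seed = 1L, reference = NULL, threshold = 0.9,
                       stages = c("annot", "filter", "split", "stat",
                                  "nmf", "compare")) {
  all_stages <- c("annot", "filter", "split", "stat", "nmf", "compare")
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (rank_min > rank_max)
    stop("invalid rank range: rank_min (", rank_min,
         ") exceeds rank_max (", rank_max, ")")
  if (flank < 1L) stop("flank must be >= 1")
  if (max_freq < 0 || max_freq > 1) stop("max_freq must lie in [0, 1]")
  cfg <- list(input = input, genome = genome, transcripts = transcripts,
              outdir = outdir, flank = as.integer(flank), dbs = dbs,
              segdup = segdup, max_freq = max_freq, rank = rank,
              rank_min = as.integer(rank_min),
              rank_max = as.integer(rank_max),
              n_runs = as.integer(n_runs),
              survey_runs = as.integer(survey_runs),
              seed = as.integer(seed), reference = reference,
              threshold = threshold, stages = stages)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain annotate -> filter -> split -> statistics ->
#' signature extraction -> reference comparison, skipping stages not listed
#' in the configuration, and writes TSV/JSON outputs plus a machine-readable
#' `manifest.json` recording the package version, seed, parameters and
#' per-stage record counts. Re-running with the same configuration and seed
#' reproduces byte-identical outputs.
#'
#' @param config A `run_config` object (or a YAML path).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "mutspectra",
                   version = as.character(utils::packageVersion("mutspectra")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("outdir", "stages"))],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message("[", stage, "] done")
  }

  x <- read_variants(config$input)
  genome <- read_genome(config$genome)
  tx <- if (!is.null(config$transcripts))
    read_transcripts(config$transcripts) else NULL

  if ("annot" %in% config$stages) {
    x <- annotate_cohort(x, genome, tx, flank = config$flank)
    .write_tsv(x, file.path(config$outdir, "annotated.tsv"))
    note("annot", records_in = nrow(x), records_out = nrow(x),
         classified_sbs = sum(!is.na(x$class96)))
  }

  if ("filter" %in% config$stages) {
    dbs <- lapply(config$dbs, read_polymorphism_db)
    regions <- if (!is.null(config$segdup)) read_regions(config$segdup)
               else NULL
    fr <- filter_variants(x, dbs = dbs, regions = regions,
                          max_freq = config$max_freq)
    .write_tsv(fr$kept, file.path(config$outdir, "kept.tsv"))
    .write_tsv(fr$removed, file.path(config$outdir, "removed.tsv"))
    note("filter", records_in = nrow(x), records_out = nrow(fr$kept),
         removed = as.list(fr$report))
    x <- fr$kept
  }

  if ("split" %in% config$stages) {
    parts <- split_by_sample(x)
    sdir <- file.path(config$outdir, "samples")
    dir.create(sdir, showWarnings = FALSE)
    for (s in names(parts))
      write_variants(parts[[s]], file.path(sdir, paste0(s, ".tsv")))
    note("split", records_in = nrow(x), records_out = nrow(x),
         n_samples = length(parts))
  }

  stats_out <- NULL
  if ("stat" %in% config$stages) {
    if (!"variant_type" %in% names(x))
      x <- annotate_cohort(x, genome, tx, flank = config$flank)
    stats_out <- count_spectra(x)
    write_matrix_tsv(stats_out$matrix96,
                     file.path(config$outdir, "matrix96.tsv"))
    write_matrix_tsv(stats_out$sbs6, file.path(config$outdir, "sbs6.tsv"),
                     label_header = "type")
    write_matrix_tsv(pool_samples(stats_out$matrix96),
                     file.path(config$outdir, "matrix96_pool.tsv"))
    sb <- NULL
    if (!is.null(tx)) {
      sb <- strand_bias(x, level = "6")
      .write_tsv(sb, file.path(config$outdir, "strand_bias6.tsv"))
    }
    cd <- chrom_distribution(x, stats::setNames(Biostrings::width(genome),
                                                names(genome)))
    .write_tsv(cd$table, file.path(config$outdir, "chrom_distribution.tsv"))
    jsonlite::write_json(list(pearson_r = cd$r,
                              n_samples = ncol(stats_out$matrix96),
                              n_classified = sum(stats_out$matrix96)),
                         file.path(config$outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("stat", records_in = nrow(x),
         classified_sbs = sum(stats_out$matrix96),
         strand_bias = !is.null(sb))
  }

  fact <- NULL
  if ("nmf" %in% config$stages) {
    if (is.null(stats_out))
      stop("the nmf stage requires the stat stage")
    V <- stats_out$matrix96
    rank <- config$rank
    ranks <- seq(config$rank_min, min(config$rank_max, ncol(V) - 1L))
    if (is.null(rank) || length(ranks) > 1L) {
      sv <- rank_survey(V, ranks = ranks, n_runs = config$survey_runs,
                        seed = config$seed)
      .write_tsv(sv$table, file.path(config$outdir, "rank_survey.tsv"))
      if (is.null(rank))
        rank <- if (is.na(sv$suggested_rank)) min(ranks)
                else sv$suggested_rank
    }
    fact <- factorize(V, rank = rank, n_runs = config$n_runs,
                      seed = config$seed)
    write_matrix_tsv(fact$W, file.path(config$outdir, "signatures.tsv"))
    write_matrix_tsv(fact$H, file.path(config$outdir, "contributions.tsv"),
                     label_header = "signature")
    cs <- contributions_and_clusters(fact)
    .write_tsv(cs$per_sample, file.path(config$outdir, "sample_summary.tsv"))
    .write_tsv(cs$clusters, file.path(config$outdir, "cluster_summary.tsv"))
    note("nmf", rank = rank, n_runs = config$n_runs,
         divergence = fact$divergence, n_samples = ncol(fact$H))
  }

  if ("compare" %in% config$stages && !is.null(config$reference)) {
    if (is.null(fact))
      stop("the compare stage requires the nmf stage")
    ref <- read_signature_matrix(config$reference)
    cmp <- compare_signatures(fact, ref, threshold = config$threshold)
    write_matrix_tsv(cmp$similarity,
                     file.path(config$outdir, "similarity.tsv"),
                     label_header = "signature")
    note("compare", n_extracted = nrow(cmp$similarity),
         n_reference = ncol(cmp$similarity),
         n_matched = sum(lengths(cmp$matches) > 0))
  }

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
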