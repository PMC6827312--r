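# End-to-end orchestration: sequences -> hits -> threshold scan ->
# delineation -> HMM library -> precision/recall, with reproducible
# outputs and a run report.

#' Assemble a pipeline configuration
#'
#' Defaults follow the published workflow: threshold grid `1e-5..1e-120`
#' in 5-log steps, delineation at `1e-55`, minimum subfamily size 20 with
#' diversity at the class rank, metanode merging at `1e-85`, redundancy
#' reduction at 75%, and the HMM assignment rule (ceiling `1e-30`, fold
#' `1e10`).
#'
#' @param fasta path to the input FASTA (required unless `records` given).
#' @param taxonomy optional taxonomy TSV path.
#' @param coverage optional coverage TSV path (enables the fragment filter).
#' @param blast_tabular optional precomputed BLAST tabular file; when set,
#'   the internal aligner is skipped.
#' @param thresholds E-value grid.
#' @param delineation_threshold threshold of the partition used to call
#'   subfamilies.
#' @param min_size,diversity_rank,min_distinct,overrides subfamily rules
#'   (see [delineate()]).
#' @param merge_threshold metanode merge threshold.
#' @param redundancy_identity redundancy-reduction identity.
#' @param hmm_ceiling,hmm_fold assignment-rule parameters.
#' @param seed seed for all randomized steps.
#' @param outdir output directory (`NULL` = write nothing).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, taxonomy = NULL, coverage = NULL,
                            blast_tabular = NULL,
                            thresholds = default_threshold_grid(),
                            delineation_threshold = 1e-55,
                            min_size = 20, diversity_rank = "class",
                            min_distinct = 2, overrides = integer(0),
                            merge_threshold = 1e-85,
                            redundancy_identity = 0.75,
                            hmm_ceiling = 1e-30, hmm_fold = 1e10,
                            seed = 1, outdir = NULL) {
  structure(list(fasta = fasta, taxonomy = taxonomy, coverage = coverage,
                 blast_tabular = blast_tabular, thresholds = thresholds,
                 delineation_threshold = delineation_threshold,
                 min_size = min_size, diversity_rank = diversity_rank,
                 min_distinct = min_distinct, overrides = overrides,
                 merge_threshold = merge_threshold,
                 redundancy_identity = redundancy_identity,
                 hmm_ceiling = hmm_ceiling, hmm_fold = hmm_fold,
                 seed = seed, outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys are the arguments of [pipeline_config()]; unknown keys
#' are rejected. `thresholds` may be given as a vector or as a list with
#' `from`, `to`, `step` exponents (e.g. 5, 120, 5).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$thresholds) && is.list(vals$thresholds))
    vals$thresholds <- 10^-seq(vals$thresholds$from, vals$thresholds$to,
                               by = vals$thresholds$step)
  do.call(pipeline_config, vals)
}

#' Run the full subfamily-delineation pipeline
#'
#' Stages: read sequences and metadata; fragment filter (when coverage is
#' supplied); all-vs-all alignment or BLAST import; threshold scan;
#' delineation at the chosen threshold; S+1 HMM library build; scan and
#' assignment; precision/recall against the delineation. Identical config
#' and seed give identical outputs.
#'
#' @param config a `pipeline_config`, or a path to a YAML config file.
#' @param records optionally, a [seq_records] data frame used instead of
#'   reading `config$fasta` (handy for synthetic data).
#' @param coverage optionally, a named coverage vector overriding
#'   `config$coverage`.
#' @return an `ssn_pipeline` report: list with `config`, `counts`
#'   (per-stage record counts), `scan`, `delineation`, `library`,
#'   `assignments`, `pr`, and `fragments`.
#' @export
run_pipeline <- function(config, records = NULL, coverage = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(records)) {
    if (is.null(config$fasta)) stop("config$fasta or records required")
    records <- read_fasta(config$fasta)
    if (!is.null(config$taxonomy))
      records <- attach_taxonomy(records, config$taxonomy)
  }
  n_input <- nrow(records)
  fragments <- records[0, , drop = FALSE]
  if (is.null(coverage) && !is.null(config$coverage))
    coverage <- read_coverage(config$coverage)
  if (!is.null(coverage)) {
    fl <- filter_fragments(records, coverage)
    records <- fl$kept
    fragments <- fl$fragments
  }
  hits <- if (!is.null(config$blast_tabular))
    parse_blast_tabular(config$blast_tabular)
  else
    all_vs_all(records, ceiling = max(config$thresholds))
  scan <- threshold_scan(hits, records$id, thresholds = config$thresholds)
  part <- partition_at(scan, config$delineation_threshold)
  delineation <- delineate(part, records, min_size = config$min_size,
                           diversity_rank = config$diversity_rank,
                           min_distinct = config$min_distinct,
                           overrides = config$overrides)
  library <- build_hmm_library(records, delineation$membership,
                               identity = config$redundancy_identity,
                               calib_seed = config$seed)
  assignments <- assign_subfamily(records, library,
                                  best_ceiling = config$hmm_ceiling,
                                  fold = config$hmm_fold)
  reference <- delineation$membership
  pr <- evaluate_library(assignments,
                         setNames(as.character(reference), names(reference)),
                         fold = config$hmm_fold)
  report <- structure(list(
    config = config,
    counts = c(input = n_input, kept = nrow(records),
               fragments = nrow(fragments),
               classified = sum(!is.na(delineation$membership)),
               nonclassified = length(delineation$nonclassified)),
    records = records, hits = hits, scan = scan, delineation = delineation,
    library = library,
    assignments = assignments, pr = pr, fragments = fragments,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "ssn_pipeline")
  if (!is.null(config$outdir)) write_pipeline_outputs(report)
  report
}

#' @noRd
write_pipeline_outputs <- function(report) {
  dir.create(report$config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(report$config$outdir, f)
  export_scan_summary(report$scan, p("scan_summary.tsv"))
  export_partitions(report$scan, p("partitions.tsv"))
  export_membership(report$delineation, p("membership.tsv"))
  export_subfamily_summary(report$delineation, p("subfamilies.tsv"))
  export_assignments(report$assignments, p("assignments.tsv"))
  export_pr_table(report$pr, p("pr_table.tsv"))
  write_hmm_library(report$library, p("hmm_library.jsonl"))
  # representatives for external tree building
  write_blast_tabular(report$hits, p("hits.tsv"))
  export_representatives(report$delineation, report$records,
                         p("representatives.fasta"),
                         seed = report$config$seed)
  g <- build_graph(report$hits, report$records$id,
                   report$config$delineation_threshold)
  export_edge_list(g, p("edges.tsv"))
  export_graphml(g, p("network.graphml"))
  writeLines(yaml::as.yaml(report$config[!vapply(report$config, is.null,
                                                 TRUE)]),
             p("config_echo.yaml"))
  invisible(report)
}

#' Export sampled subfamily representatives as FASTA
#'
#' Samples up to `n` members per subfamily (all members when smaller; see
#' [sample_representatives()]) and writes them to one FASTA file for
#' external tree building.
#'
#' @param call a `subfamily_call`.
#' @param records the [seq_records] the call was made on.
#' @param path output FASTA path.
#' @param n per-subfamily sample size (default 30).
#' @param seed base seed; subfamily `i` uses `seed + i`.
#' @return `path`, invisibly.
#' @export
export_representatives <- function(call, records, path, n = 30, seed = 1) {
  reps <- unlist(lapply(seq_len(nrow(call$subfamilies)), function(i)
    sample_representatives(call$subfamilies$members[[i]], n = n,
                           seed = seed + i)))
  write_fasta(records[match(reps, records$id), , drop = FALSE], path)
  invisible(path)
}

#' @export
print.ssn_pipeline <- function(x, ...) {
  cat("<ssn_pipeline> run report\n")
  cat(sprintf("  sequences: %d input, %d kept, %d fragments\n",
              x$counts["input"], x$counts["kept"], x$counts["fragments"]))
  cat(sprintf("  delineation at E = %g: %d subfamilies, %d classified, %d nonclassified (%.1f%%)\n",
              x$config$delineation_threshold,
              nrow(x$delineation$subfamilies), x$counts["classified"],
              x$counts["nonclassified"],
              100 * x$delineation$classified_fraction))
  i30 <- which.min(abs(log10(x$pr$cutoff) - log10(x$config$hmm_ceiling)))
  cat(sprintf("  HMM library: %d models; precision %.3f, recall %.3f at ceiling %g\n",
              length(x$library$models), x$pr$precision[i30],
              x$pr$recall[i30], x$pr$cutoff[i30]))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}
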