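# End-to-end pipeline orchestration: demux -> score -> QC -> hit call, and
# filter -> fold -> stratify -> test.

#' Load and validate a run configuration
#'
#' A run configuration is a YAML file (or equivalent named list) with blocks:
#' `inputs` (paths: `fastq`, `barcode_tsv`, `barcode_config`, `panel_fasta`,
#' `panel_windows`, `plate_map`, `pool_design`, `variant_table`),
#' `scoring` (`k`, `fixed_threshold`, `min_depth`, `q`),
#' `recovery` (`min_depth`, `r`, `pseudocount`, `continuity`),
#' `output_dir`, `seed`, `log_level`. Unknown keys are rejected.
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated list of class `run_config` with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_bad("run config not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  known <- c("inputs", "scoring", "recovery", "output_dir", "seed",
             "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop_bad("unknown run config key '%s'", unknown[1])
  }
  scoring_defaults <- list(k = 5, fixed_threshold = NULL, min_depth = 200L,
                           q = 2)
  recovery_defaults <- list(min_depth = 5L, r = 2, pseudocount = 0.5,
                            continuity = TRUE)
  sc <- utils::modifyList(scoring_defaults, config$scoring %||% list())
  rc <- utils::modifyList(recovery_defaults, config$recovery %||% list())
  if (sc$k < 0) stop_bad("scoring k must be non-negative")
  if (sc$min_depth < 0) stop_bad("scoring min_depth must be non-negative")
  if (rc$r <= 0) stop_bad("recovery fold threshold r must be positive")
  if (rc$pseudocount < 0) stop_bad("recovery pseudocount must be non-negative")
  structure(list(
    inputs = config$inputs %||% list(),
    scoring = sc, recovery = rc,
    output_dir = config$output_dir %||% ".",
    seed = config$seed %||% NA_integer_,
    log_level = config$log_level %||% "info"
  ), class = "run_config")
}

require_input <- function(cfg, key, stage) {
  path <- cfg$inputs[[key]]
  if (is.null(path)) {
    stop_bad("[%s] run config is missing inputs.%s", stage, key)
  }
  missing <- path[!file.exists(path)]
  if (length(missing) > 0) {
    stop_bad("[%s] input file not found: %s", stage, missing[1])
  }
  path
}

log_line <- function(lines, fmt, ...) c(lines, sprintf(fmt, ...))

#' Run the screen pipeline: FASTQ to hit table
#'
#' Validates every configured input before touching the FASTQ, then runs
#' demultiplexing and allele counting, per-well MAF scoring, plate QC,
#' null-model fitting on the pooled DMSO controls, and hit calling, writing
#' all artifacts (counts TSV, per-well MAF TSV, null-model JSON, plate QC
#' TSV, hits TSV, JSON run summary and a plain-text run log) under
#' `output_dir`.
#'
#' @param config A [run_config()] (or YAML path / named list coercible to
#'   one).
#' @return Invisibly, a list with the in-memory results (`counts`, `mafs`,
#'   `qc`, `null`, `hits`) and `paths` of the written artifacts.
#' @export
run_screen_pipeline <- function(config) {
  cfg <- run_config(config)
  # fail on configuration before any FASTQ is read
  plate_map_path <- require_input(cfg, "plate_map", "screen")
  barcode_tsv <- require_input(cfg, "barcode_tsv", "screen")
  barcode_config <- require_input(cfg, "barcode_config", "screen")
  panel_fasta <- require_input(cfg, "panel_fasta", "screen")
  panel_windows <- require_input(cfg, "panel_windows", "screen")
  pool_design_path <- require_input(cfg, "pool_design", "screen")
  fastq <- require_input(cfg, "fastq", "screen")

  pm <- read_plate_map(plate_map_path)
  manifest <- read_barcode_manifest(barcode_tsv, barcode_config)
  panel <- read_amplicon_panel(panel_fasta, panel_windows)
  design <- read_pool_design(pool_design_path)

  counts <- count_alleles(fastq, manifest, panel, plate_map = pm)
  mafs <- score_wells(counts, design, panel, plate_map = pm,
                      min_depth = cfg$scoring$min_depth)
  qc <- plate_qc(mafs, pm, q = cfg$scoring$q)
  null <- fit_null(mafs, k = cfg$scoring$k, plate_map = pm, qc = qc,
                   fixed_threshold = cfg$scoring$fixed_threshold)
  hits <- call_hits(mafs, null, pm, qc = qc)

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_screen_outputs(mafs, null, hits, qc, cfg$output_dir)
  counts_path <- file.path(cfg$output_dir, "allele_counts.tsv")
  summary_path <- file.path(cfg$output_dir, "run_summary.json")
  write_allele_counts(counts, counts_path, summary_path)
  paths <- c(paths, counts = counts_path, summary = summary_path)

  t <- counts$totals
  lines <- character(0)
  lines <- log_line(lines, "screen pipeline")
  lines <- log_line(lines, "config hash: %s", rlang::hash(cfg))
  lines <- log_line(lines, "reads seen: %d; assigned: %d (%.2f%% unassigned)",
                    t[["reads_seen"]], t[["reads_assigned"]],
                    100 * t[["reads_unassigned"]] / max(t[["reads_seen"]], 1))
  lines <- log_line(lines, "classified: %d; ambiguous: %d; unclassified: %d",
                    t[["reads_classified"]], t[["reads_ambiguous"]],
                    t[["reads_unclassified"]])
  for (i in seq_len(nrow(null))) {
    lines <- log_line(lines, "threshold[%s] = %.6g", null$allele_id[i],
                      null$threshold[i])
  }
  lines <- log_line(lines, "plates passing QC: %d / %d", sum(qc$passed),
                    nrow(qc))
  lines <- log_line(lines, "hits: %d / %d library wells", sum(hits$is_hit),
                    nrow(hits))
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  writeLines(lines, log_path)
  if (cfg$log_level %in% c("info", "debug")) inform(paste(lines, collapse = "\n"))

  invisible(list(counts = counts, mafs = mafs, qc = qc, null = null,
                 hits = hits, paths = c(paths, log = log_path)))
}

#' Run the recovery pipeline: variant table to class summary and test
#'
#' Reads the per-variant count table, applies the inclusion filter, computes
#' fold changes and recovery calls, stratifies by mutation class, and — when
#' the table carries an `nmd_predicted` column — runs the two-proportion
#' chi-squared test comparing recovery between variants predicted and not
#' predicted to undergo NMD. Artifacts (recovery TSV, class summary TSV,
#' test JSON, run log) are written under `output_dir`. An empty variant
#' table produces empty outputs and a warning, not an error.
#'
#' @param config A [run_config()] (or YAML path / named list); needs
#'   `inputs.variant_table`.
#' @return Invisibly, a list with `recovery`, `class_summary`, `test` (or
#'   `NULL`), and `paths`.
#' @export
run_recovery_pipeline <- function(config) {
  cfg <- run_config(config)
  path <- require_input(cfg, "variant_table", "recovery")
  variants <- read_variant_table(path)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  if (nrow(variants) == 0) {
    warn("variant table is empty; writing empty outputs")
    empty <- recovery_fold(variants, r = cfg$recovery$r,
                           pseudocount = cfg$recovery$pseudocount,
                           min_depth = cfg$recovery$min_depth)
    paths <- write_recovery_outputs(empty, stratify_recovery(empty),
                                    test = NULL, dir = cfg$output_dir)
    return(invisible(list(recovery = empty,
                          class_summary = stratify_recovery(empty),
                          test = NULL, paths = paths)))
  }

  rec <- recovery_fold(variants, r = cfg$recovery$r,
                       pseudocount = cfg$recovery$pseudocount,
                       min_depth = cfg$recovery$min_depth)
  summary <- stratify_recovery(rec)
  test <- NULL
  if ("nmd_predicted" %in% names(rec)) {
    pass <- rec[rec$pass_filter, ]
    pred <- pass[pass$nmd_predicted %in% TRUE, ]
    other <- pass[pass$nmd_predicted %in% FALSE, ]
    if (nrow(pred) > 0 && nrow(other) > 0 &&
        (sum(pred$recovered) + sum(other$recovered)) > 0 &&
        (sum(!pred$recovered) + sum(!other$recovered)) > 0) {
      test <- two_proportion_test(sum(pred$recovered), nrow(pred),
                                  sum(other$recovered), nrow(other),
                                  continuity = cfg$recovery$continuity)
    }
  }
  paths <- write_recovery_outputs(rec, summary, test, cfg$output_dir)

  lines <- c(
    "recovery pipeline",
    sprintf("config hash: %s", rlang::hash(cfg)),
    sprintf("variants: %d read, %d pass filter, %d recovered",
            nrow(variants), sum(rec$pass_filter), sum(rec$recovered)),
    utils::capture.output(print(as.data.frame(summary)))
  )
  if (!is.null(test)) {
    lines <- c(lines, sprintf(
      "NMD-predicted vs other recovery: chi2 = %.6g, p = %.3g",
      test$statistic, test$p_value))
  }
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  writeLines(lines, log_path)
  if (cfg$log_level %in% c("info", "debug")) inform(paste(lines, collapse = "\n"))

  invisible(list(recovery = rec, class_summary = summary, test = test,
                 paths = c(paths, log = log_path)))
}
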