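# End-to-end orchestration: QC -> ensemble -> aggregation -> model
# comparison, with all artefacts written atomically to an output
# directory. Deterministic given the master seed.

#' Pipeline configuration
#'
#' @param cohort A `pr_cohort`, or a path to a cohort CSV (then `meta` is
#'   required).
#' @param output_dir Output directory (created if absent).
#' @param meta Variable metadata for a CSV cohort.
#' @param reference_af Optional reference allele-count table (data frame or
#'   CSV path; see [fisher_af_filter()]) enabling the QC filter.
#' @param models Optional list of extra models to compare (specs, registry
#'   names, or paths to model JSON files). By default the pipeline compares
#'   the aggregated combined model with its genetic-only and clinical-only
#'   subsets.
#' @param n_replicates Number of ensemble replicates (default 10000).
#' @param master_seed Master seed for the replicate schedule.
#' @param direction,force,donor_mode,stratify Passed to [run_ensemble()].
#' @param qc_alpha Fisher retention threshold (default 0.01).
#' @param fdr_level FDR level used to annotate the report (default 0.05).
#' @return A validated list of class `pr_config`.
#' @export
run_config <- function(cohort, output_dir, meta = NULL, reference_af = NULL,
                       models = list(), n_replicates = 10000,
                       master_seed = 1, direction = "both",
                       force = character(),
                       donor_mode = "all_controls", stratify = FALSE,
                       qc_alpha = 0.01, fdr_level = 0.05) {
  stopifnot(n_replicates >= 1, qc_alpha > 0, qc_alpha < 1,
            fdr_level > 0, fdr_level < 1)
  if (is.character(cohort)) {
    if (is.null(meta)) {
      stop("a CSV cohort needs `meta` (variable_meta())", call. = FALSE)
    }
    cohort <- read_cohort_csv(cohort, meta)
  }
  stopifnot(inherits(cohort, "pr_cohort"))
  if (is.character(reference_af)) {
    reference_af <- readr::read_csv(reference_af, show_col_types = FALSE)
  }
  models <- lapply(models, function(m) {
    if (is.character(m) && file.exists(m)) read_model_json(m) else m
  })
  structure(list(cohort = cohort, output_dir = output_dir,
                 reference_af = reference_af, models = models,
                 n_replicates = n_replicates,
                 master_seed = as.integer(master_seed),
                 direction = direction, force = force,
                 donor_mode = donor_mode, stratify = stratify,
                 qc_alpha = qc_alpha, fdr_level = fdr_level),
            class = "pr_config")
}

write_atomic <- function(path, writer) {
  tmp <- tempfile("pr_", tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Run the full pipeline
#'
#' Stages: cohort validation; allele-frequency QC (when a reference is
#' configured) with discarded variants removed from the candidate set;
#' descriptive table; the split/impute/stepwise ensemble and its
#' median-coefficient aggregation; and a shared-schedule AUC comparison of
#' the final combined model against its genetic-only and clinical-only
#' subsets plus any configured extra models. Any configured model that
#' references a QC-discarded variant aborts the run with the variant
#' named. All files are written atomically; a rerun with an identical
#' configuration reproduces them byte-identically.
#'
#' Outputs in `output_dir`: `qc_report.csv`, `descriptives.csv`,
#' `ensemble_model.json`, `ensemble_table.csv`, `ensemble_report.csv`,
#' `auc_comparison.csv`, `roc_points.csv`, `replicate_log.jsonl`,
#' `pipeline_log.txt`.
#'
#' @param config A `pr_config` from [run_config()].
#' @return Invisibly, a list with the in-memory results (`qc`, `ensemble`,
#'   `replicates`, `comparison`, `descriptives`) and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pr_config"))
  cohort <- config$cohort
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  violations <- stage("validate", validate_cohort(cohort))
  if (nrow(violations) > 0) {
    stop("pipeline stage 'validate' failed: ",
         paste(violations$message, collapse = "; "), call. = FALSE)
  }
  log_add("cohort: ", sum(cohort$data$status == 1), " cases / ",
          sum(cohort$data$status == 0), " controls, ",
          nrow(cohort$meta), " variables")

  candidates <- cohort$meta$name
  qc <- NULL
  if (!is.null(config$reference_af)) {
    qc <- stage("qc", fisher_af_filter(cohort, config$reference_af,
                                       alpha = config$qc_alpha))
    dropped <- discarded_variants(qc)
    candidates <- setdiff(candidates, dropped)
    log_add("qc: discarded ", length(dropped), " variant(s)",
            if (length(dropped) > 0)
              paste0(" (", paste(dropped, collapse = ", "), ")") else "")
    paths$qc_report <- write_atomic(
      file.path(config$output_dir, "qc_report.csv"),
      function(p) readr::write_csv(as_tibble(qc), p, na = "NA"))
    for (m in config$models) {
      spec <- if (is.character(m)) registry_model(m) else m
      bad <- intersect(spec$variables$name, dropped)
      if (length(bad) > 0) {
        stop("pipeline stage 'qc' failed: model '", spec$name,
             "' uses QC-discarded variant(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }

  desc <- stage("descriptives", descriptive_table(cohort))
  paths$descriptives <- write_atomic(
    file.path(config$output_dir, "descriptives.csv"),
    function(p) readr::write_csv(desc, p, na = "NA"))

  replicates <- stage("ensemble", run_ensemble(
    cohort, candidates = candidates, n_replicates = config$n_replicates,
    master_seed = config$master_seed, direction = config$direction,
    force = config$force, donor_mode = config$donor_mode,
    stratify = config$stratify))
  ensemble <- stage("aggregate", aggregate_ensemble(replicates))
  log_add("ensemble: ", config$n_replicates, " replicates, mean model size ",
          sprintf("%.2f", ensemble$mean_model_size), ", ",
          sum(ensemble$table$median_coefficient != 0),
          " variables in the final model, ", sum(replicates$skipped),
          " non-converged moves skipped")

  paths$replicate_log <- write_atomic(
    file.path(config$output_dir, "replicate_log.jsonl"),
    function(p) {
      con <- file(p, open = "wt")
      on.exit(close(con))
      for (i in seq_len(nrow(replicates))) {
        writeLines(jsonlite::toJSON(list(
          replicate = replicates$replicate[i], seed = replicates$seed[i],
          aic = replicates$aic[i],
          selected = replicates$selected[[i]]), auto_unbox = TRUE,
          digits = NA), con)
      }
    })
  paths$ensemble_model <- write_atomic(
    file.path(config$output_dir, "ensemble_model.json"),
    function(p) write_model_json(ensemble, p))
  paths$ensemble_table <- write_atomic(
    file.path(config$output_dir, "ensemble_table.csv"),
    function(p) readr::write_csv(ensemble$table, p, na = "NA"))
  paths$ensemble_report <- write_atomic(
    file.path(config$output_dir, "ensemble_report.csv"),
    function(p) readr::write_csv(ensemble_report(ensemble, cohort), p,
                                 na = "NA"))

  final <- ensemble$table$variable[ensemble$table$median_coefficient != 0]
  kinds <- cohort$meta$kind[match(final, cohort$meta$name)]
  compare <- list()
  if (length(final) > 0) compare$combined <- model_spec("combined", final)
  if (any(kinds == "genotype")) {
    compare$genetic <- model_spec("genetic", final[kinds == "genotype"])
  }
  if (any(kinds != "genotype")) {
    compare$clinical <- model_spec("clinical", final[kinds != "genotype"])
  }
  compare <- c(compare, config$models)
  comparison <- stage("compare", compare_models(
    cohort, compare, n_replicates = config$n_replicates,
    master_seed = config$master_seed, donor_mode = config$donor_mode,
    stratify = config$stratify, roc = "pooled"))
  log_add("compare: ", paste(sprintf("%s %.3f", comparison$table$model,
                                     comparison$table$median_auc),
                             collapse = "; "))
  paths$auc_comparison <- write_atomic(
    file.path(config$output_dir, "auc_comparison.csv"),
    function(p) readr::write_csv(comparison$table, p, na = "NA"))
  paths$roc_points <- write_atomic(
    file.path(config$output_dir, "roc_points.csv"),
    function(p) readr::write_csv(comparison$roc, p, na = "NA"))

  log_add("seeds: master ", config$master_seed, ", replicate schedule ",
          "seed_i = master XOR i")
  paths$log <- write_atomic(
    file.path(config$output_dir, "pipeline_log.txt"),
    function(p) writeLines(log_lines, p))

  invisible(list(qc = qc, descriptives = desc, replicates = replicates,
                 ensemble = ensemble, comparison = comparison,
                 paths = paths))
}
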