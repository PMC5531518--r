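# The resampling ensemble: for each replicate, hot-deck impute, split in
# half, run stepwise-AIC selection on the training half; then aggregate
# the replicate models into the final median-coefficient model.
# A variable unselected in a replicate contributes a zero coefficient
# (odds ratio 1) to the median; its standard error is the median over the
# replicates where it WAS selected.

#' Run the split/impute/stepwise replicate ensemble
#'
#' @param cohort A `pr_cohort` (may contain missing values; every variable
#'   with missing cells needs a non-empty control donor pool).
#' @param candidates Candidate variables for selection; default all cohort
#'   variables.
#' @param n_replicates Number of replicates (the emulated design uses
#'   10,000).
#' @param master_seed Master seed; replicate `i` runs under
#'   [replicate_seed()]`(master_seed, i)`, making results independent of
#'   execution order and prefix-consistent in `n_replicates`.
#' @param direction,force Passed to [stepwise_select()].
#' @param donor_mode `"all_controls"` (default: impute the full cohort from
#'   all observed control values, then split) or `"train_controls"`
#'   (split first, donors restricted to training-half controls).
#' @param stratify Stratify splits by case status (default `FALSE`).
#' @param verbose Print a progress line every 100 replicates.
#' @return A tibble of class `pr_replicates`, one row per replicate with
#'   list-columns `selected`, `coef` (named, intercept included) and `se`,
#'   plus `aic`, `n_selected`, `skipped`, `seed`.
#' @export
run_ensemble <- function(cohort, candidates = NULL, n_replicates = 10000,
                         master_seed = 1, direction = "both",
                         force = character(),
                         donor_mode = c("all_controls", "train_controls"),
                         stratify = FALSE, verbose = FALSE) {
  stopifnot(inherits(cohort, "pr_cohort"), n_replicates >= 1)
  donor_mode <- match.arg(donor_mode)
  candidates <- candidates %||% cohort$meta$name
  check_donor_pools(cohort, candidates)
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    rs <- replicate_seed(master_seed, i)
    step <- tryCatch({
      rd <- replicate_data(cohort, rs, donor_mode, stratify, i)
      train <- rd$imputed$data[rd$imputed$data$sample_id %in%
                                 rd$split$train_ids, ]
      stepwise_select(train, status = train$status, candidates = candidates,
                      direction = direction, force = force)
    }, error = function(e) {
      stop("replicate ", i, " (seed ", rs, "): ", conditionMessage(e),
           call. = FALSE)
    })
    rows[[i]] <- tibble(
      replicate = i, seed = rs,
      n_selected = length(step$selected),
      aic = step$fit$aic, skipped = step$skipped,
      selected = list(step$selected),
      coef = list(step$fit$coefficients),
      se = list(step$fit$se))
    if (verbose && i %% 100 == 0) {
      message("replicate ", i, "/", n_replicates)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "candidates") <- candidates
  attr(out, "master_seed") <- as.integer(master_seed)
  attr(out, "direction") <- direction
  attr(out, "force") <- force
  attr(out, "donor_mode") <- donor_mode
  attr(out, "stratify") <- stratify
  class(out) <- c("pr_replicates", class(out))
  out
}

check_donor_pools <- function(cohort, candidates) {
  ctrl <- cohort$data$status == 0
  for (v in candidates) {
    x <- cohort$data[[v]]
    if (anyNA(x) && all(is.na(x[ctrl]))) {
      stop("variable '", v, "' has missing values but no observed control ",
           "value to donate (see validate_cohort())", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Aggregate replicate models into the final median-coefficient model
#'
#' Per candidate variable: the median coefficient over *all* replicates
#' with unselected replicates contributing zero; the median standard error
#' over the replicates where the variable was selected; the selection
#' frequency; the odds ratio `exp(median coefficient)` with a 95% Wald
#' interval `exp(median_coefficient +/- 1.96 * median_se)`; a two-sided
#' Wald p-value; and a Benjamini-Hochberg q-value across all candidates
#' with a defined p. The intercept is the median intercept over all
#' replicates so the final model can emit calibrated probabilities.
#'
#' @param replicates A `pr_replicates` from [run_ensemble()].
#' @param candidates Candidate set (defaults to the attribute recorded by
#'   [run_ensemble()]).
#' @return An object of class `pr_ensemble`: `table` (per-variable tibble),
#'   `intercept`, `n_replicates`, `mean_model_size`.
#' @export
aggregate_ensemble <- function(replicates, candidates = NULL) {
  stopifnot(nrow(replicates) >= 1)
  candidates <- candidates %||% attr(replicates, "candidates")
  if (is.null(candidates)) {
    stop("no candidate set recorded; pass `candidates`", call. = FALSE)
  }
  n_rep <- nrow(replicates)
  coefs <- matrix(0, n_rep, length(candidates),
                  dimnames = list(NULL, candidates))
  ses <- matrix(NA_real_, n_rep, length(candidates),
                dimnames = list(NULL, candidates))
  intercepts <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    b <- replicates$coef[[i]]
    s <- replicates$se[[i]]
    intercepts[i] <- b[["(Intercept)"]]
    sel <- intersect(names(b), candidates)
    coefs[i, sel] <- b[sel]
    ses[i, sel] <- s[sel]
  }
  selected <- !is.na(ses)
  med_coef <- unname(apply(coefs, 2, median))
  sel_freq <- unname(colMeans(selected))
  med_se <- vapply(seq_along(candidates), function(j) {
    s <- ses[selected[, j], j]
    if (length(s) == 0) NA_real_ else median(s)
  }, numeric(1))
  z <- med_coef / med_se
  p <- 2 * pnorm(-abs(z))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  tbl <- tibble(
    variable = candidates,
    median_coefficient = med_coef,
    median_se = med_se,
    selection_frequency = sel_freq,
    or = exp(med_coef),
    ci_lo = exp(med_coef - 1.96 * med_se),
    ci_hi = exp(med_coef + 1.96 * med_se),
    p = p, q = q)
  structure(list(table = tbl, intercept = median(intercepts),
                 n_replicates = n_rep,
                 mean_model_size = mean(replicates$n_selected)),
            class = "pr_ensemble")
}

#' @export
print.pr_ensemble <- function(x, ...) {
  nz <- sum(x$table$median_coefficient != 0)
  cat("<pr_ensemble> ", x$n_replicates, " replicates; mean model size ",
      sprintf("%.1f", x$mean_model_size), "; final model: ", nz,
      " variables with non-zero median coefficient\n", sep = "")
  print(dplyr::arrange(dplyr::filter(x$table, .data$median_coefficient != 0),
                       .data$p), n = 20)
  invisible(x)
}

#' @describeIn aggregate_ensemble Per-variable aggregation table.
#' @param x A `pr_ensemble`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pr_ensemble <- function(x, ...) x$table

#' @describeIn aggregate_ensemble One-row ensemble summary.
#' @exportS3Method generics::glance
glance.pr_ensemble <- function(x, ...) {
  tibble(n_replicates = x$n_replicates,
         n_final = sum(x$table$median_coefficient != 0),
         mean_model_size = x$mean_model_size,
         intercept = x$intercept)
}

#' Publication-style ensemble report
#'
#' The per-variable aggregation table augmented with cohort descriptives:
#' effect allele and per-group allele frequencies for genotypes, per-group
#' means or percentages for clinical variables.
#'
#' @param ensemble A `pr_ensemble`.
#' @param cohort The `pr_cohort` the ensemble was run on.
#' @param final_only Keep only variables with non-zero median coefficient.
#' @return A tibble, one row per variable, ordered by p-value.
#' @export
ensemble_report <- function(ensemble, cohort, final_only = TRUE) {
  stopifnot(inherits(ensemble, "pr_ensemble"), inherits(cohort, "pr_cohort"))
  desc <- descriptive_table(cohort)
  tbl <- ensemble$table
  if (final_only) tbl <- tbl[tbl$median_coefficient != 0, ]
  meta <- cohort$meta
  out <- dplyr::left_join(tbl, meta, by = c(variable = "name")) |>
    dplyr::left_join(desc[c("variable", "case_pct", "control_pct",
                            "case_mean", "control_mean", "case_freq",
                            "control_freq")], by = "variable")
  out$case_stat <- dplyr::coalesce(out$case_freq, out$case_mean,
                                   out$case_pct)
  out$control_stat <- dplyr::coalesce(out$control_freq, out$control_mean,
                                      out$control_pct)
  dplyr::arrange(
    out[c("variable", "gene_label", "effect_allele", "kind", "case_stat",
          "control_stat", "or", "ci_lo", "ci_hi", "p", "q",
          "selection_frequency")],
    .data$p)
}
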