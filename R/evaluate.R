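# Out-of-sample evaluation: per-replicate test-half AUC under the same
# seed schedule as the ensemble, and the published-model comparison
# harness. Compared models share every replicate's imputation and split,
# so AUC differences are paired.

resolve_spec <- function(model, cohort) {
  if (is.character(model) && length(model) == 1) model <- registry_model(model)
  if (inherits(model, "pr_ensemble")) {
    model <- as_model_spec(model, refit = TRUE)
  }
  stopifnot(inherits(model, "pr_model_spec"))
  missing_vars <- setdiff(model$variables$name, cohort$meta$name)
  if (length(missing_vars) > 0) {
    stop("model '", model$name, "' references variable(s) absent from the ",
         "cohort: ", paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  model
}

# Evaluate several specs on a shared replicate schedule.
eval_replicates <- function(cohort, specs, n_replicates, master_seed,
                            donor_mode = "all_controls", stratify = FALSE,
                            pool_roc = FALSE) {
  stopifnot(n_replicates >= 1)
  aucs <- matrix(NA_real_, n_replicates, length(specs),
                 dimnames = list(NULL, names(specs)))
  nonconv <- setNames(integer(length(specs)), names(specs))
  pooled <- if (pool_roc) {
    lapply(specs, function(s) list(case = vector("list", n_replicates),
                                   ctrl = vector("list", n_replicates)))
  }
  for (i in seq_len(n_replicates)) {
    rs <- replicate_seed(master_seed, i)
    rd <- replicate_data(cohort, rs, donor_mode, stratify, i)
    dat <- rd$imputed$data
    in_train <- dat$sample_id %in% rd$split$train_ids
    train <- dat[in_train, ]; test <- dat[!in_train, ]
    for (k in seq_along(specs)) {
      spec <- specs[[k]]
      vars <- spec$variables$name
      Xte <- as.matrix(test[vars])
      if (spec$refit) {
        Xtr <- as.matrix(train[vars])
        f <- fit_logistic_matrix(cbind(1, Xtr), train$status)
        if (!f$converged) {
          # refit separated/singular: fall back to a capped-iteration fit so
          # the replicate still scores; ranking is robust to inflation
          f <- fit_logistic_matrix(cbind(1, Xtr), train$status, maxit = 25L)
          nonconv[k] <- nonconv[k] + 1L
          if (!f$converged && is.null(f$coefficients)) {
            next # singular design: AUC stays NA for this replicate
          }
        }
        beta <- f$coefficients[-1]
      } else {
        beta <- spec$variables$coefficient
      }
      score <- drop(Xte %*% beta)
      cs <- score[test$status == 1]; ns <- score[test$status == 0]
      aucs[i, k] <- auc_rank(cs, ns)
      if (pool_roc) {
        pooled[[k]]$case[[i]] <- cs
        pooled[[k]]$ctrl[[i]] <- ns
      }
    }
  }
  list(aucs = aucs, nonconverged = nonconv, pooled = pooled)
}

summarise_aucs <- function(x) {
  x <- x[!is.na(x)]
  c(median = median(x), lo = unname(quantile(x, 0.025)),
    hi = unname(quantile(x, 0.975)))
}

#' Cross-validated out-of-sample AUC of one model
#'
#' For each replicate (same seed schedule as [run_ensemble()]): impute,
#' split, estimate the model on the training half (refit models are fitted
#' by logistic MLE on their fixed variable set; fixed-coefficient models
#' are applied as-is), score the test half by the linear predictor and
#' compute the rank AUC. The final AUC is the median across replicates
#' with a 2.5/97.5 percentile interval.
#'
#' @param cohort A `pr_cohort`.
#' @param model A `pr_model_spec`, a registry name (see
#'   [registry_model()]), or a `pr_ensemble` (evaluated as a refit model
#'   over its final variable set).
#' @param n_replicates,master_seed,donor_mode,stratify As in
#'   [run_ensemble()].
#' @return An object of class `pr_auc`: `model`, `aucs` (per replicate),
#'   `median_auc`, `ci`, `n_replicates`, `nonconverged`.
#' @export
crossval_evaluate <- function(cohort, model, n_replicates = 10000,
                              master_seed = 1,
                              donor_mode = c("all_controls",
                                             "train_controls"),
                              stratify = FALSE) {
  stopifnot(inherits(cohort, "pr_cohort"))
  donor_mode <- match.arg(donor_mode)
  spec <- resolve_spec(model, cohort)
  res <- eval_replicates(cohort, setNames(list(spec), spec$name),
                         n_replicates, master_seed, donor_mode, stratify)
  s <- summarise_aucs(res$aucs[, 1])
  structure(list(model = spec$name, aucs = res$aucs[, 1],
                 median_auc = s[["median"]],
                 ci = c(s[["lo"]], s[["hi"]]),
                 n_replicates = n_replicates,
                 nonconverged = res$nonconverged[[1]]),
            class = "pr_auc")
}

#' @export
print.pr_auc <- function(x, ...) {
  cat("<pr_auc> '", x$model, "': median AUC ",
      sprintf("%.3f", x$median_auc), " (",
      sprintf("%.3f", x$ci[1]), "-", sprintf("%.3f", x$ci[2]), ") over ",
      x$n_replicates, " replicates\n", sep = "")
  invisible(x)
}

#' @describeIn crossval_evaluate Per-replicate AUC table.
#' @param x A `pr_auc`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pr_auc <- function(x, ...) {
  tibble(model = x$model, replicate = seq_along(x$aucs), auc = x$aucs)
}

#' @describeIn crossval_evaluate One-row summary (median AUC and CI).
#' @exportS3Method generics::glance
glance.pr_auc <- function(x, ...) {
  tibble(model = x$model, median_auc = x$median_auc,
         ci_lo = x$ci[1], ci_hi = x$ci[2],
         n_replicates = x$n_replicates, nonconverged = x$nonconverged)
}

#' Compare several models on a shared replicate schedule
#'
#' Every model is evaluated on the same sequence of imputations and
#' splits, so per-replicate AUC differences are paired. ROC curves are
#' rendered two ways: `"pooled"` concatenates all test-half scores across
#' replicates into one curve per model; `"averaged"` interpolates each
#' replicate's curve on a common false-positive-rate grid and averages the
#' true-positive rates vertically.
#'
#' @param cohort A `pr_cohort`.
#' @param models A list of models (specs, registry names, or ensembles),
#'   optionally named.
#' @param n_replicates,master_seed,donor_mode,stratify As in
#'   [run_ensemble()].
#' @param roc `"pooled"`, `"averaged"`, `"both"` or `"none"`.
#' @return An object of class `pr_comparison`: `table` (model, median_auc,
#'   ci_lo, ci_hi, nonconverged), `aucs` (long per-replicate tibble), and
#'   `roc` (long tibble with columns `model`, `rendering`, `fpr`, `tpr`,
#'   or `NULL`).
#' @export
compare_models <- function(cohort, models, n_replicates = 10000,
                           master_seed = 1,
                           donor_mode = c("all_controls", "train_controls"),
                           stratify = FALSE,
                           roc = c("pooled", "averaged", "both", "none")) {
  stopifnot(inherits(cohort, "pr_cohort"))
  donor_mode <- match.arg(donor_mode)
  roc <- match.arg(roc)
  if (!is.list(models)) models <- as.list(models)
  specs <- lapply(models, resolve_spec, cohort = cohort)
  nm <- names(specs) %||% rep("", length(specs))
  blank <- !nzchar(nm)
  nm[blank] <- vapply(specs[blank], function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate model names in comparison: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(specs) <- nm
  res <- eval_replicates(cohort, specs, n_replicates, master_seed,
                         donor_mode, stratify, pool_roc = roc != "none")
  tbl <- purrr::map_dfr(nm, function(m) {
    s <- summarise_aucs(res$aucs[, m])
    tibble(model = m, median_auc = s[["median"]], ci_lo = s[["lo"]],
           ci_hi = s[["hi"]], nonconverged = res$nonconverged[[m]])
  })
  aucs <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(res$aucs), replicate = dplyr::row_number()),
    -"replicate", names_to = "model", values_to = "auc")
  roc_tbl <- NULL
  if (roc != "none") {
    roc_tbl <- purrr::map_dfr(nm, function(m) {
      p <- res$pooled[[m]]
      if (length(unlist(p$case)) == 0 || length(unlist(p$ctrl)) == 0) {
        warning("model '", m, "' produced no test scores; ROC omitted",
                call. = FALSE)
        return(NULL)
      }
      out <- NULL
      if (roc %in% c("pooled", "both")) {
        rc <- roc_curve(unlist(p$case), unlist(p$ctrl))
        out <- dplyr::bind_rows(out, dplyr::mutate(rc, model = m,
                                                   rendering = "pooled"))
      }
      if (roc %in% c("averaged", "both")) {
        grid <- seq(0, 1, by = 0.01)
        tprs <- vapply(seq_along(p$case), function(i) {
          if (is.null(p$case[[i]])) return(rep(NA_real_, length(grid)))
          rc <- roc_curve(p$case[[i]], p$ctrl[[i]])
          stats::approx(rc$fpr, rc$tpr, xout = grid, ties = max,
                        rule = 2)$y
        }, numeric(length(grid)))
        out <- dplyr::bind_rows(out, tibble(fpr = grid,
                                            tpr = rowMeans(tprs, na.rm = TRUE),
                                            model = m,
                                            rendering = "averaged"))
      }
      out
    })
  }
  structure(list(table = tbl, aucs = aucs, roc = roc_tbl,
                 n_replicates = n_replicates,
                 master_seed = as.integer(master_seed)),
            class = "pr_comparison")
}

#' @export
print.pr_comparison <- function(x, ...) {
  cat("<pr_comparison> ", nrow(x$table), " models over ", x$n_replicates,
      " shared replicates\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @describeIn compare_models Per-replicate AUC table (long format).
#' @param x A `pr_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pr_comparison <- function(x, ...) x$aucs

#' @describeIn compare_models The comparison table (one row per model).
#' @exportS3Method generics::glance
glance.pr_comparison <- function(x, ...) x$table

#' Score individuals with a fitted model
#'
#' Linear predictor `intercept + sum(beta * x)` per row, and the logistic
#' probability when the model carries an intercept (without one, only the
#' score column is returned, since the probability is not identified).
#'
#' @param model A `pr_model_spec` with coefficients, or a `pr_ensemble`
#'   (its final median-coefficient model is used).
#' @param data A data frame of covariate rows containing every model
#'   variable.
#' @param on_missing `"error"` (default) or `"na"`: how to treat rows with
#'   missing model covariates.
#' @return The input rows as a tibble with appended `score` (and
#'   `probability` when an intercept is present).
#' @export
score_individuals <- function(model, data, on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  if (inherits(model, "pr_ensemble")) model <- as_model_spec(model)
  stopifnot(inherits(model, "pr_model_spec"))
  if (anyNA(model$variables$coefficient)) {
    stop("model '", model$name, "' has no coefficients to score with",
         call. = FALSE)
  }
  data <- as_tibble(data)
  missing_vars <- setdiff(model$variables$name, names(data))
  if (length(missing_vars) > 0) {
    stop("data lacks model variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[model$variables$name])
  if (anyNA(X) && on_missing == "error") {
    stop("missing covariate values; use on_missing = \"na\" to propagate",
         call. = FALSE)
  }
  base <- model$intercept %||% 0
  data$score <- base + drop(X %*% model$variables$coefficient)
  if (!is.null(model$intercept)) data$probability <- plogis(data$score)
  data
}
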