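# Synthetic case-control cohort generator. Genotypes are drawn under
# Hardy-Weinberg equilibrium (two independent Bernoulli allele draws at the
# population effect-allele frequency); clinical covariates from truncated
# normal / Bernoulli distributions; disease status from a logistic model on
# the generated covariates. Population individuals are simulated and
# accepted by status until the case and control quotas are filled
# (case-control sampling), which leaves every log odds ratio identifiable
# and only the intercept a nuisance.

#' Specify a simulated variant
#'
#' @param name Variant identifier.
#' @param effect_allele_freq Population effect-allele frequency in `[0, 1]`.
#' @param true_or Per-allele odds ratio of the generating disease model
#'   (1 for null/decoy variants). `true_log_or` overrides it if given.
#' @param true_log_or Per-allele log odds ratio.
#' @param effect_allele Allele symbol carried into the cohort metadata.
#' @param gene_label Optional gene annotation.
#' @return A one-row tibble (rows of several calls can be `bind_rows`-ed).
#' @export
variant_spec <- function(name, effect_allele_freq, true_or = 1,
                         true_log_or = log(true_or), effect_allele = "A",
                         gene_label = NA_character_) {
  stopifnot(all(effect_allele_freq >= 0 & effect_allele_freq <= 1))
  tibble(name = as.character(name),
         effect_allele_freq = as.numeric(effect_allele_freq),
         true_log_or = as.numeric(true_log_or),
         effect_allele = as.character(effect_allele),
         gene_label = as.character(gene_label))
}

#' Specify a simulated clinical covariate
#'
#' Binary covariates are Bernoulli(`prevalence`); continuous covariates are
#' normal(`mean`, `sd`) redrawn until inside `[lower, upper]`.
#'
#' @param name Covariate name.
#' @param kind `"binary"` or `"continuous"`.
#' @param prevalence Population prevalence (binary).
#' @param mean,sd,lower,upper Distribution parameters (continuous).
#' @param true_or,true_log_or Per-unit odds ratio / log odds ratio in the
#'   generating disease model.
#' @return A one-row tibble.
#' @export
clinical_spec <- function(name, kind, prevalence = NA_real_, mean = NA_real_,
                          sd = NA_real_, lower = -Inf, upper = Inf,
                          true_or = 1, true_log_or = log(true_or)) {
  stopifnot(kind %in% c("binary", "continuous"))
  if (kind == "binary") {
    stopifnot(!is.na(prevalence), prevalence >= 0, prevalence <= 1)
  } else {
    stopifnot(!is.na(mean), !is.na(sd), sd > 0, lower < upper)
  }
  tibble(name = as.character(name), kind = kind,
         prevalence = as.numeric(prevalence), mean = as.numeric(mean),
         sd = as.numeric(sd), lower = as.numeric(lower),
         upper = as.numeric(upper), true_log_or = as.numeric(true_log_or))
}

#' Default simulation panel at study scale
#'
#' The nine VTE-associated SNPs at their published per-allele odds ratios
#' and control effect-allele frequencies, the four clinical risk factors
#' (age, BMI, smoking, family history of VTE) at their published control
#' distributions and per-unit odds ratios, plus `n_decoys` null SNPs with
#' frequencies drawn uniformly on `decoy_freq_range` standing in for the
#' unnamed remainder of a 46-SNP genotyping panel.
#'
#' @param n_decoys Number of null decoy SNPs (default 30).
#' @param decoy_freq_range Frequency range for decoys.
#' @param decoy_seed Seed for the decoy frequency draw (kept separate from
#'   the cohort seed so the panel is a fixed design object).
#' @param comparison_snps Also include rs2066865 (FGG) and rs2036914 (F11)
#'   as null variants so published comparison panels resolve against the
#'   generated cohort.
#' @return A list with tibbles `variants` and `clinicals`.
#' @export
study_panel <- function(n_decoys = 30, decoy_freq_range = c(0.05, 0.5),
                        decoy_seed = 20170727L, comparison_snps = FALSE) {
  variants <- dplyr::bind_rows(
    variant_spec("rs6025",     0.02, 6.46, effect_allele = "A", gene_label = "F5"),
    variant_spec("rs1799963",  0.01, 5.32, effect_allele = "A", gene_label = "F2"),
    variant_spec("rs8176719",  0.41, 1.52, effect_allele = "I", gene_label = "ABO"),
    variant_spec("rs2289252",  0.42, 1.34, effect_allele = "T", gene_label = "F11"),
    variant_spec("rs1799853",  0.12, 1.54, effect_allele = "T", gene_label = "CYP2C9"),
    variant_spec("rs9574",     0.51, 1.25, effect_allele = "G", gene_label = "PROCR"),
    variant_spec("rs8176750",  0.07, 0.60, effect_allele = "D", gene_label = "ABO"),
    variant_spec("rs4379368",  0.08, 1.35, effect_allele = "T", gene_label = "SUGCT"),
    variant_spec("rs710446",   0.43, 1.22, effect_allele = "G", gene_label = "KNG1")
  )
  if (comparison_snps) {
    variants <- dplyr::bind_rows(
      variants,
      variant_spec("rs2066865", 0.24, 1, effect_allele = "A", gene_label = "FGG"),
      variant_spec("rs2036914", 0.47, 1, effect_allele = "C", gene_label = "F11")
    )
  }
  if (n_decoys > 0) {
    freqs <- withr::with_seed(decoy_seed,
      runif(n_decoys, decoy_freq_range[1], decoy_freq_range[2]))
    variants <- dplyr::bind_rows(
      variants,
      variant_spec(sprintf("decoy_%02d", seq_len(n_decoys)), freqs, 1)
    )
  }
  clinicals <- dplyr::bind_rows(
    clinical_spec("age", "continuous", mean = 31.5, sd = 9.0,
                  lower = 18, upper = 51, true_or = 1.01),
    clinical_spec("bmi", "continuous", mean = 23, sd = 4.2,
                  lower = 17.5, upper = 33.5, true_or = 1.07),
    clinical_spec("smoking", "binary", prevalence = 0.25, true_or = 1.63),
    clinical_spec("family_history", "binary", prevalence = 0.15,
                  true_or = 2.13)
  )
  list(variants = variants, clinicals = clinicals)
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- which(x < lower | x > upper)
    if (length(bad) == 0) return(x)
    x[bad] <- rnorm(length(bad), mean, sd)
  }
  stop("truncation bounds [", lower, ", ", upper,
       "] reject nearly all draws", call. = FALSE)
}

#' Generate a synthetic case-control cohort
#'
#' Simulates population individuals (HWE genotypes, clinical covariates),
#' assigns disease status with probability
#' `plogis(baseline_logit + sum(true_log_or * x))`, and accepts individuals
#' by status until exactly `n_cases` cases and `n_controls` controls are
#' collected. With `baseline_logit = NULL` the intercept is auto-calibrated
#' by a mean-field approximation so the population prevalence is roughly
#' `target_prevalence` — under case-control sampling the intercept only
#' affects simulation efficiency, not the identifiable log odds ratios.
#'
#' @param variants Tibble of [variant_spec()] rows (may be zero rows).
#' @param clinicals Tibble of [clinical_spec()] rows, or `NULL`.
#' @param n_cases,n_controls Target group sizes.
#' @param baseline_logit Intercept of the generating logistic model;
#'   `NULL` to auto-calibrate.
#' @param target_prevalence Approximate population prevalence used by the
#'   auto-calibration. The default 0.01 reflects a rare outcome (on the
#'   order of a percent over the exposure window), which keeps the
#'   case-control sampling in the rare-disease regime where the odds
#'   ratio approximates the risk ratio and case allele frequencies show
#'   the full published enrichment.
#' @param seed Integer seed; identical inputs and seed give a byte-identical
#'   cohort.
#' @param max_batches Simulation cap: generation aborts if the quotas are
#'   not filled after this many batches (extreme `baseline_logit`).
#' @return A list with elements `cohort` (a `pr_cohort`, cases first) and
#'   `truth` (a `pr_truth` ground-truth record).
#' @examples
#' panel <- study_panel(n_decoys = 2)
#' gen <- generate_cohort(panel$variants, panel$clinicals,
#'                        n_cases = 50, n_controls = 50, seed = 1)
#' gen$cohort
#' @export
generate_cohort <- function(variants, clinicals = NULL, n_cases = 794,
                            n_controls = 828, baseline_logit = NULL,
                            target_prevalence = 0.01, seed = 1,
                            max_batches = 400) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  if (is.null(clinicals)) clinicals <- clinical_spec("..none", "binary",
                                                     prevalence = 0)[0, ]
  stopifnot(all(variants$effect_allele_freq >= 0),
            all(variants$effect_allele_freq <= 1))
  lor <- c(variants$true_log_or, clinicals$true_log_or)
  if (is.null(baseline_logit)) {
    # mean-field calibration: subtract the mean linear-predictor contribution
    mean_x <- c(2 * variants$effect_allele_freq,
                ifelse(clinicals$kind == "binary", clinicals$prevalence,
                       clinicals$mean))
    baseline_logit <- qlogis(target_prevalence) - sum(mean_x * lor)
  }
  set.seed(as.integer(seed))
  p_var <- nrow(variants)
  p_cli <- nrow(clinicals)
  # size batches so the rarer group usually fills in one or two passes
  prev_guess <- min(0.999, max(1e-4, target_prevalence))
  batch <- min(200000L, max(5000L,
    ceiling(1.3 * max(n_cases / prev_guess,
                      n_controls / (1 - prev_guess)))))
  got_case <- got_ctrl <- list()
  need_case <- n_cases; need_ctrl <- n_controls
  for (b in seq_len(max_batches)) {
    X <- matrix(0, batch, p_var + p_cli)
    for (j in seq_len(p_var)) {
      X[, j] <- rbinom(batch, 2L, variants$effect_allele_freq[j])
    }
    for (j in seq_len(p_cli)) {
      X[, p_var + j] <- if (clinicals$kind[j] == "binary") {
        rbinom(batch, 1L, clinicals$prevalence[j])
      } else {
        rtrunc_norm(batch, clinicals$mean[j], clinicals$sd[j],
                    clinicals$lower[j], clinicals$upper[j])
      }
    }
    pr <- plogis(baseline_logit + drop(X %*% lor))
    y <- rbinom(batch, 1L, pr)
    if (need_case > 0 && any(y == 1)) {
      take <- head(which(y == 1), need_case)
      got_case[[length(got_case) + 1]] <- X[take, , drop = FALSE]
      need_case <- need_case - length(take)
    }
    if (need_ctrl > 0 && any(y == 0)) {
      take <- head(which(y == 0), need_ctrl)
      got_ctrl[[length(got_ctrl) + 1]] <- X[take, , drop = FALSE]
      need_ctrl <- need_ctrl - length(take)
    }
    if (need_case == 0 && need_ctrl == 0) break
  }
  if (need_case > 0 || need_ctrl > 0) {
    stop("case/control accrual exceeded ", max_batches, " batches; ",
         "baseline_logit ", signif(baseline_logit, 4), " is too extreme",
         call. = FALSE)
  }
  X <- rbind(do.call(rbind, got_case), do.call(rbind, got_ctrl))
  var_names <- c(variants$name, clinicals$name)
  colnames(X) <- var_names
  data <- tibble(
    sample_id = c(sprintf("case_%04d", seq_len(n_cases)),
                  sprintf("ctrl_%04d", seq_len(n_controls))),
    status = rep(c(1L, 0L), c(n_cases, n_controls))
  )
  data <- dplyr::bind_cols(data, as_tibble(X))
  meta <- dplyr::bind_rows(
    if (p_var > 0) variable_meta(variants$name, "genotype",
                                 effect_allele = variants$effect_allele,
                                 gene_label = variants$gene_label),
    if (p_cli > 0) variable_meta(clinicals$name, clinicals$kind)
  )
  truth <- structure(
    list(variables = tibble(name = var_names,
                            true_log_or = lor, true_or = exp(lor)),
         intercept = baseline_logit, seed = as.integer(seed),
         n_cases = n_cases, n_controls = n_controls,
         target_prevalence = target_prevalence),
    class = "pr_truth")
  list(cohort = cohort(data, meta), truth = truth)
}

#' @export
print.pr_truth <- function(x, ...) {
  cat("<pr_truth> generating model: intercept ", signif(x$intercept, 4),
      ", ", nrow(x$variables), " variables (",
      sum(x$variables$true_log_or != 0), " non-null), seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pr_truth <- function(x, ...) x$variables

#' Write / read a ground-truth record as JSON
#' @param truth A `pr_truth`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_truth_json()` returns a `pr_truth`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "pr_truth"))
  obj <- list(intercept = truth$intercept, seed = truth$seed,
              n_cases = truth$n_cases, n_controls = truth$n_controls,
              target_prevalence = truth$target_prevalence,
              variables = purrr::pmap(truth$variables,
                function(name, true_log_or, true_or) {
                  list(name = name, true_log_or = true_log_or)
                }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lor <- purrr::map_dbl(obj$variables, "true_log_or")
  structure(
    list(variables = tibble(name = purrr::map_chr(obj$variables, "name"),
                            true_log_or = lor, true_or = exp(lor)),
         intercept = obj$intercept, seed = obj$seed,
         n_cases = obj$n_cases, n_controls = obj$n_controls,
         target_prevalence = obj$target_prevalence),
    class = "pr_truth")
}

#' Mask cells of a cohort as missing
#'
#' Applies structured missingness (every cell of the given sample subsets
#' and variable lists becomes missing) and then missing-completely-at-random
#' noise at rate `mcar_rate` over the remaining cells. Status and sample
#' identifiers are never masked.
#'
#' @param cohort A `pr_cohort`.
#' @param mcar_rate Per-cell independent missingness probability in `[0, 1]`.
#' @param masks List of structured masks, each a
#'   `list(samples = <ids>, variables = <names>)`.
#' @param seed Optional seed for the MCAR draw; `NULL` uses the current RNG
#'   state.
#' @return The masked `pr_cohort`.
#' @seealso [study_missingness()] for the biased-control mask of the study
#'   design this generator emulates.
#' @export
apply_missingness <- function(cohort, mcar_rate = 0, masks = list(),
                              seed = NULL) {
  stopifnot(inherits(cohort, "pr_cohort"),
            mcar_rate >= 0, mcar_rate <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  data <- cohort$data
  vars <- cohort$meta$name
  structured <- matrix(FALSE, nrow(data), length(vars),
                       dimnames = list(NULL, vars))
  for (m in masks) {
    bad_s <- setdiff(m$samples, data$sample_id)
    if (length(bad_s) > 0) {
      stop("mask references unknown sample(s): ",
           paste(head(bad_s, 5), collapse = ", "), call. = FALSE)
    }
    bad_v <- setdiff(m$variables, vars)
    if (length(bad_v) > 0) {
      stop("mask references unknown variable(s): ",
           paste(bad_v, collapse = ", "), call. = FALSE)
    }
    structured[data$sample_id %in% m$samples, m$variables] <- TRUE
  }
  for (j in seq_along(vars)) {
    v <- vars[j]
    miss <- structured[, j]
    if (mcar_rate > 0) {
      mcar <- runif(nrow(data)) < mcar_rate
      miss <- miss | (mcar & !structured[, j])
    }
    data[[v]][miss] <- NA_real_
  }
  cohort$data <- data
  cohort
}

#' Structured missingness of the emulated study design
#'
#' The study's biased control subset (recruited through thrombophilia
#' screening) had family history and the two thrombophilia genotypes
#' (rs6025, rs1799963) set to missing. This helper builds the equivalent
#' mask for a generated cohort: the first `n_masked_controls` controls and
#' whichever of the three variables exist in the cohort.
#'
#' @param cohort A `pr_cohort`.
#' @param n_masked_controls Number of controls to mask (default 523).
#' @param variables Variables to mask where present.
#' @return A one-element list suitable for `masks` in [apply_missingness()].
#' @export
study_missingness <- function(cohort, n_masked_controls = 523,
                              variables = c("family_history", "rs6025",
                                            "rs1799963")) {
  stopifnot(inherits(cohort, "pr_cohort"))
  ctrl <- cohort$data$sample_id[cohort$data$status == 0]
  n_masked_controls <- min(n_masked_controls, length(ctrl))
  list(list(samples = head(ctrl, n_masked_controls),
            variables = intersect(variables, cohort$meta$name)))
}
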