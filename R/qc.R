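# Pre-analysis QC: allele-frequency concordance against a reference panel
# (two-sided Fisher exact test on 2x2 allele-count tables), and a
# descriptive case/control comparison table with Wilcoxon rank-sum p-values.

#' Effect-allele frequency of a variant
#'
#' Missing genotypes are excluded from both numerator and denominator:
#' `freq = sum(genotype) / (2 * n_nonmissing)`.
#'
#' @param cohort A `pr_cohort`.
#' @param variants Genotype variable name(s); default all genotype variants.
#' @param subset `"all"`, `"cases"` or `"controls"`.
#' @return A tibble with columns `variant`, `subset`, `freq`, `n_alleles`.
#' @export
allele_frequency <- function(cohort, variants = NULL,
                             subset = c("all", "cases", "controls")) {
  stopifnot(inherits(cohort, "pr_cohort"))
  subset <- match.arg(subset)
  geno <- cohort$meta$name[cohort$meta$kind == "genotype"]
  variants <- variants %||% geno
  bad <- setdiff(variants, geno)
  if (length(bad) > 0) {
    stop("not genotype variant(s) of this cohort: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- switch(subset, all = rep(TRUE, nrow(cohort$data)),
                 cases = cohort$data$status == 1,
                 controls = cohort$data$status == 0)
  purrr::map_dfr(variants, function(v) {
    x <- cohort$data[[v]][keep]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      stop("'", v, "' has no observed genotype in subset '", subset, "'",
           call. = FALSE)
    }
    tibble(variant = v, subset = subset,
           freq = sum(x) / (2 * length(x)), n_alleles = 2L * length(x))
  })
}

ref_counts <- function(reference) {
  reference <- as_tibble(reference)
  if (all(c("effect_count", "other_count") %in% names(reference))) {
    out <- reference[c("variant", "effect_count", "other_count")]
  } else if (all(c("effect_freq", "n_samples") %in% names(reference))) {
    # frequency + sample-size form: convert to nearest integer allele counts
    eff <- round(2 * reference$n_samples * reference$effect_freq)
    out <- tibble(variant = reference$variant, effect_count = eff,
                  other_count = 2 * reference$n_samples - eff)
  } else {
    stop("reference needs columns (variant, effect_count, other_count) ",
         "or (variant, effect_freq, n_samples)", call. = FALSE)
  }
  if (any(out$effect_count < 0 | out$other_count < 0)) {
    stop("negative reference allele counts", call. = FALSE)
  }
  out
}

#' Allele-frequency concordance filter
#'
#' Compares the control effect-allele counts of every genotype variant
#' against user-supplied reference panel counts with a two-sided Fisher
#' exact test, and retains a variant only when `p > alpha` (a variant whose
#' p-value equals `alpha` exactly is discarded). Variants absent from the
#' reference pass by default with a warning.
#'
#' @param cohort A `pr_cohort`.
#' @param reference Data frame with columns `variant`, `effect_count`,
#'   `other_count` (allele counts), or `variant`, `effect_freq`, `n_samples`
#'   (converted by rounding).
#' @param alpha Retention threshold (default 0.01).
#' @return A tibble of class `pr_af_qc`: one row per genotype variant with
#'   cohort/reference counts and frequencies, `fisher_p` and `keep`.
#' @export
fisher_af_filter <- function(cohort, reference, alpha = 0.01) {
  stopifnot(inherits(cohort, "pr_cohort"), alpha > 0, alpha < 1)
  reference <- ref_counts(reference)
  geno <- cohort$meta$name[cohort$meta$kind == "genotype"]
  ctrl <- cohort$data$status == 0
  rows <- purrr::map_dfr(geno, function(v) {
    x <- cohort$data[[v]][ctrl]
    x <- x[!is.na(x)]
    eff <- sum(x)
    oth <- 2 * length(x) - eff
    i <- match(v, reference$variant)
    if (is.na(i)) {
      return(tibble(variant = v, cohort_effect = eff, cohort_other = oth,
                    cohort_freq = eff / max(1, eff + oth),
                    ref_effect = NA_real_, ref_other = NA_real_,
                    ref_freq = NA_real_, fisher_p = NA_real_, keep = TRUE))
    }
    re <- reference$effect_count[i]; ro <- reference$other_count[i]
    p <- fisher.test(matrix(c(eff, oth, re, ro), nrow = 2))$p.value
    tibble(variant = v, cohort_effect = eff, cohort_other = oth,
           cohort_freq = eff / max(1, eff + oth),
           ref_effect = re, ref_other = ro, ref_freq = re / max(1, re + ro),
           fisher_p = p, keep = p > alpha)
  })
  missing_ref <- rows$variant[is.na(rows$fisher_p)]
  if (length(missing_ref) > 0) {
    warning("no reference counts for: ",
            paste(missing_ref, collapse = ", "),
            "; retained without a test", call. = FALSE)
  }
  attr(rows, "alpha") <- alpha
  class(rows) <- c("pr_af_qc", class(rows))
  rows
}

#' Variants discarded by the allele-frequency filter
#' @param qc A `pr_af_qc` from [fisher_af_filter()].
#' @return Character vector of discarded variant names.
#' @export
discarded_variants <- function(qc) {
  stopifnot(inherits(qc, "pr_af_qc"))
  qc$variant[!qc$keep]
}

wilcox_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  all_vals <- c(x, y)
  if (length(unique(all_vals)) == 1) return(1) # all tied: no evidence
  ties <- anyDuplicated(all_vals) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
}

#' Case/control descriptive comparison
#'
#' One row per cohort variable: counts and percentages (over non-missing
#' samples) for binary variables, mean/SD/range for continuous variables,
#' effect-allele frequency for genotypes, and a two-sided Wilcoxon rank-sum
#' p-value comparing cases to controls on the non-missing values (exact for
#' tie-free groups of at most 25, normal approximation with tie and
#' continuity correction otherwise).
#'
#' @param cohort A `pr_cohort`.
#' @return A tibble with per-group summaries and `p_value`.
#' @export
descriptive_table <- function(cohort) {
  stopifnot(inherits(cohort, "pr_cohort"))
  case <- cohort$data$status == 1
  purrr::map_dfr(seq_len(nrow(cohort$meta)), function(i) {
    v <- cohort$meta$name[i]; kind <- cohort$meta$kind[i]
    x <- cohort$data[[v]][case]; y <- cohort$data[[v]][!case]
    xo <- x[!is.na(x)]; yo <- y[!is.na(y)]
    row <- tibble(variable = v, kind = kind,
                  case_n = length(xo), control_n = length(yo),
                  case_count = NA_real_, control_count = NA_real_,
                  case_pct = NA_real_, control_pct = NA_real_,
                  case_mean = NA_real_, control_mean = NA_real_,
                  case_sd = NA_real_, control_sd = NA_real_,
                  case_min = NA_real_, case_max = NA_real_,
                  control_min = NA_real_, control_max = NA_real_,
                  case_freq = NA_real_, control_freq = NA_real_,
                  p_value = wilcox_p(x, y))
    if (kind == "binary") {
      row$case_count <- sum(xo); row$control_count <- sum(yo)
      row$case_pct <- 100 * sum(xo) / max(1, length(xo))
      row$control_pct <- 100 * sum(yo) / max(1, length(yo))
    } else if (kind == "continuous") {
      if (length(xo) > 0) {
        row$case_mean <- mean(xo); row$case_sd <- stats::sd(xo)
        row$case_min <- min(xo); row$case_max <- max(xo)
      }
      if (length(yo) > 0) {
        row$control_mean <- mean(yo); row$control_sd <- stats::sd(yo)
        row$control_min <- min(yo); row$control_max <- max(yo)
      }
    } else {
      if (length(xo) > 0) row$case_freq <- sum(xo) / (2 * length(xo))
      if (length(yo) > 0) row$control_freq <- sum(yo) / (2 * length(yo))
    }
    row
  })
}
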