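# Post-hoc pairwise interaction screen of a final model. This is a check
# on the selected main-effects model, not part of the stepwise search:
# each pair of final-model variables is tested by adding its product term
# to the full main-effects fit and reading the Wald statistic.

#' Pairwise interaction screen of a selected model
#'
#' For every pair of the given variables, fits the logistic model with all
#' main effects plus that single product term on a hot-deck-imputed copy
#' of the cohort, and reports the interaction coefficient with its Wald
#' z, p-value, and Benjamini-Hochberg q across the screened pairs.
#'
#' @param cohort A `pr_cohort`.
#' @param variables Variables whose pairs are screened; defaults to the
#'   final model of `ensemble` when given.
#' @param ensemble Optional `pr_ensemble` supplying the final variable set.
#' @param seed Seed for the single imputation (ignored if the cohort is
#'   complete).
#' @return A tibble with one row per pair: `var1`, `var2`, `estimate`,
#'   `se`, `statistic`, `p`, `q` (`NA` row when the augmented fit does not
#'   converge).
#' @export
interaction_screen <- function(cohort, variables = NULL, ensemble = NULL,
                               seed = 1) {
  stopifnot(inherits(cohort, "pr_cohort"))
  if (is.null(variables)) {
    if (is.null(ensemble)) {
      stop("supply `variables` or an `ensemble`", call. = FALSE)
    }
    variables <- ensemble$table$variable[ensemble$table$median_coefficient
                                         != 0]
  }
  if (length(variables) < 2) {
    stop("need at least two variables to screen pairs", call. = FALSE)
  }
  imp <- hot_deck_impute(cohort, seed = seed)
  X <- as.matrix(imp$data[variables])
  y <- imp$data$status
  pairs <- utils::combn(variables, 2)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    v1 <- pairs[1, k]; v2 <- pairs[2, k]
    Xk <- cbind(X, interaction = X[, v1] * X[, v2])
    f <- fit_logistic(Xk, y)
    if (!f$converged) {
      return(tibble(var1 = v1, var2 = v2, estimate = NA_real_,
                    se = NA_real_, statistic = NA_real_, p = NA_real_))
    }
    b <- f$coefficients[["interaction"]]
    s <- f$se[["interaction"]]
    tibble(var1 = v1, var2 = v2, estimate = b, se = s,
           statistic = b / s, p = 2 * pnorm(-abs(b / s)))
  })
  rows$q <- NA_real_
  ok <- !is.na(rows$p)
  rows$q[ok] <- p.adjust(rows$p[ok], method = "BH")
  rows
}
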