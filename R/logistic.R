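# Logistic maximum likelihood, the base learner of the stepwise ensemble.
# The IRLS iteration lives in src/irls.cpp; this wrapper adds the
# separation diagnostic and the AIC bookkeeping.

# Coefficients beyond this magnitude on any predictor are taken as
# complete/quasi-complete separation: a per-allele or per-unit log odds
# ratio above 15 (OR > 3e6) is not a finite MLE in this domain.
.separation_bound <- 15

fit_logistic_matrix <- function(X, y, start = NULL, tol = 1e-8,
                                maxit = 100L) {
  p <- ncol(X)
  if (is.null(start)) start <- numeric(p)
  res <- irls_logistic(X, y, start, tol, maxit)
  if (!isTRUE(res$converged)) {
    return(list(converged = FALSE, reason = "irls"))
  }
  beta <- drop(res$coefficients)
  se <- drop(res$se)
  if (any(abs(beta) > .separation_bound) || any(!is.finite(se))) {
    return(list(converged = FALSE, reason = "separation"))
  }
  ll <- res$loglik
  list(converged = TRUE, coefficients = setNames(beta, colnames(X)),
       se = setNames(se, colnames(X)), loglik = ll,
       aic = 2 * p - 2 * ll, iterations = res$iterations)
}

#' Fit a logistic regression by maximum likelihood
#'
#' Iteratively reweighted least squares with convergence declared when the
#' log-likelihood changes by less than `tol` (default 1e-8) or after
#' `maxit` iterations. Standard errors come from the inverse observed
#' information; `aic = 2k - 2 * loglik` with the intercept counted in `k`.
#' Complete or quasi-complete separation is reported as `converged = FALSE`
#' rather than returned as exploded coefficients.
#'
#' @param x Predictor matrix or data frame (no intercept column), or `NULL`
#'   for an intercept-only fit.
#' @param y Binary response vector (1 = case, 0 = control), no missing
#'   values.
#' @param tol,maxit Convergence controls.
#' @param start Optional starting coefficients (intercept first).
#' @return An object of class `pr_fit` with elements `coefficients`, `se`,
#'   `loglik`, `aic`, `converged`, `n`, `iterations`.
#' @examples
#' fit_logistic(NULL, c(1, 1, 0, 0)) # intercept-only: loglik = 4 * log(0.5)
#' @export
fit_logistic <- function(x, y, tol = 1e-8, maxit = 100L, start = NULL) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  if (is.null(x)) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    x <- as.matrix(x)
    if (anyNA(x)) stop("missing values in the design matrix", call. = FALSE)
    if (nrow(x) != length(y)) stop("x/y length mismatch", call. = FALSE)
    cn <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
    X <- cbind(`(Intercept)` = 1, x)
    colnames(X) <- c("(Intercept)", cn)
  }
  res <- fit_logistic_matrix(X, y, start = start, tol = tol, maxit = maxit)
  if (!res$converged) {
    return(structure(list(coefficients = NULL, se = NULL, loglik = NA_real_,
                          aic = NA_real_, converged = FALSE,
                          reason = res$reason, n = length(y),
                          iterations = NA_integer_),
                     class = "pr_fit"))
  }
  structure(c(res[c("coefficients", "se", "loglik", "aic", "iterations")],
              list(converged = TRUE, n = length(y))),
            class = "pr_fit")
}

#' @export
print.pr_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<pr_fit> did not converge (",
        if (identical(x$reason, "separation"))
          "complete or quasi-complete separation" else "IRLS failure",
        ")\n", sep = "")
    return(invisible(x))
  }
  cat("<pr_fit> ", length(x$coefficients), " coefficients, n = ", x$n,
      ", logLik = ", signif(x$loglik, 6), ", AIC = ", signif(x$aic, 6),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_logistic Per-term coefficient table (estimate, standard
#'   error, Wald z and two-sided p-value).
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pr_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = character(), estimate = double(),
                  std.error = double(), statistic = double(),
                  p.value = double()))
  }
  z <- x$coefficients / x$se
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(x$se), statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))))
}

#' @describeIn fit_logistic One-row fit summary.
#' @exportS3Method generics::glance
glance.pr_fit <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = x$aic, nobs = x$n,
         converged = x$converged,
         df = if (x$converged) length(x$coefficients) else NA_integer_)
}
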