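# Stepwise-AIC logistic model selection. Greedy bidirectional search from
# the intercept-only model: at each iteration every single-variable
# addition and deletion is scored by the AIC of its refit, and the best
# move is applied only while it strictly lowers the AIC. Moves whose refit
# does not converge (separation of a rare allele in a half cohort) are
# skipped rather than accepted with exploded coefficients.

stepwise_design <- function(data, status = NULL, candidates = NULL) {
  if (inherits(data, "pr_cohort")) {
    candidates <- candidates %||% data$meta$name
    bad <- setdiff(candidates, data$meta$name)
    if (length(bad) > 0) {
      stop("unknown candidate variable(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    status <- data$data$status
    data <- data$data
  } else {
    data <- as_tibble(data)
    status <- status %||% data$status
    candidates <- candidates %||% setdiff(names(data),
                                          c("sample_id", "status"))
  }
  X <- as.matrix(data[candidates])
  if (anyNA(X)) {
    stop("stepwise selection needs a complete (imputed) data set",
         call. = FALSE)
  }
  storage.mode(X) <- "double"
  list(X = cbind(`(Intercept)` = 1, X), y = as.numeric(status),
       candidates = candidates)
}

#' Stepwise-AIC logistic model selection
#'
#' @param data A complete `pr_cohort` (typically a training half after
#'   hot-deck imputation) or a data frame with a `status` column.
#' @param status Binary response when `data` is a plain data frame without
#'   a `status` column.
#' @param candidates Candidate variable names; defaults to every cohort
#'   variable.
#' @param direction `"both"` (default) evaluates additions and deletions at
#'   every iteration; `"forward"` additions only from the intercept-only
#'   model; `"backward"` deletions only from the full model.
#' @param force Variables included from the start and never eligible for
#'   deletion.
#' @param aic_tol A move must lower the AIC by more than this to be
#'   accepted (guards the strict-decrease rule against floating-point
#'   noise).
#' @return An object of class `pr_stepwise`: `selected` (in order of
#'   entry), `fit` (the final `pr_fit`), `aic_path` (AIC of each accepted
#'   state, strictly decreasing), `null_aic`, `skipped` (non-converged
#'   moves), `direction`, `force`.
#' @details Ties between moves with equal AIC are broken deterministically:
#'   candidate moves are scanned in lexicographic variable-name order,
#'   additions before deletions, and the first best is taken.
#' @export
stepwise_select <- function(data, status = NULL, candidates = NULL,
                            direction = c("both", "forward", "backward"),
                            force = character(), aic_tol = 1e-8) {
  direction <- match.arg(direction)
  d <- stepwise_design(data, status, candidates)
  candidates <- d$candidates
  bad_force <- setdiff(force, candidates)
  if (length(bad_force) > 0) {
    stop("force-include variable(s) not among candidates: ",
         paste(bad_force, collapse = ", "), call. = FALSE)
  }
  # column indices into d$X (1 = intercept); scan order is lexicographic
  ord <- order(candidates)
  idx_of <- setNames(seq_along(candidates) + 1L, candidates)
  forced <- unname(idx_of[force])
  sel <- if (direction == "backward") unname(idx_of[candidates[ord]])
         else unname(sort(idx_of[force]))
  fit_state <- function(cols, start = NULL) {
    fit_logistic_matrix(d$X[, c(1L, cols), drop = FALSE], d$y, start = start)
  }
  cur <- fit_state(sel)
  if (!cur$converged) {
    stop("initial stepwise model did not converge", call. = FALSE)
  }
  aic_path <- cur$aic
  skipped <- 0L
  repeat {
    best <- NULL
    consider <- function(cols, start) {
      f <- fit_state(cols, start)
      if (!f$converged) { skipped <<- skipped + 1L; return() }
      if (f$aic < cur$aic - aic_tol &&
          (is.null(best) || f$aic < best$fit$aic)) {
        best <<- list(cols = cols, fit = f)
      }
    }
    if (direction %in% c("both", "forward")) {
      for (j in idx_of[candidates[ord]]) {
        if (j %in% sel) next
        # warm start: current estimates, 0 for the entering variable
        cols <- c(sel, j)
        consider(cols, c(cur$coefficients, 0))
      }
    }
    if (direction %in% c("both", "backward")) {
      for (j in intersect(idx_of[candidates[ord]], sel)) {
        if (j %in% forced) next
        drop_pos <- match(j, sel)
        cols <- sel[-drop_pos]
        consider(cols, cur$coefficients[-(drop_pos + 1L)])
      }
    }
    if (is.null(best)) break
    sel <- best$cols
    cur <- best$fit
    aic_path <- c(aic_path, cur$aic)
  }
  final <- structure(
    c(cur[c("coefficients", "se", "loglik", "aic", "iterations")],
      list(converged = TRUE, n = length(d$y))), class = "pr_fit")
  structure(list(selected = candidates[sel - 1L], fit = final,
                 aic_path = aic_path, null_aic = NA_real_,
                 skipped = skipped, direction = direction, force = force),
            class = "pr_stepwise")
}

#' @export
print.pr_stepwise <- function(x, ...) {
  cat("<pr_stepwise> ", length(x$selected), " variables selected in ",
      length(x$aic_path) - 1, " moves (", x$direction, "); AIC ",
      signif(x$aic_path[1], 6), " -> ", signif(x$fit$aic, 6),
      if (x$skipped > 0) paste0("; ", x$skipped, " non-converged moves skipped")
      else "", "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pr_stepwise <- function(x, ...) tidy(x$fit)

#' @exportS3Method generics::glance
glance.pr_stepwise <- function(x, ...) {
  tibble(n_selected = length(x$selected), AIC = x$fit$aic,
         null_AIC = x$aic_path[1], steps = length(x$aic_path) - 1,
         skipped_moves = x$skipped)
}
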