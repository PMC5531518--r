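# ggplot2 displays for the result objects.

#' Forest plot of the aggregated ensemble model
#'
#' Odds ratios with 95% Wald intervals on a log scale, ordered by effect
#' size; the dashed line marks OR = 1.
#'
#' @param object A `pr_ensemble`.
#' @param final_only Show only variables with non-zero median coefficient.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pr_ensemble <- function(object, final_only = TRUE, ...) {
  tbl <- object$table
  if (final_only) tbl <- tbl[tbl$median_coefficient != 0, ]
  tbl <- dplyr::arrange(tbl, .data$or)
  tbl$variable <- factor(tbl$variable, levels = tbl$variable)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$or, y = .data$variable)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$selection_frequency),
                        colour = "#2c5f8a") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_size_continuous(limits = c(0, 1), range = c(1, 3)) +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL,
                  size = "selection\nfrequency",
                  title = "Median-coefficient ensemble model") +
    ggplot2::theme_minimal()
}

#' Distribution of per-replicate out-of-sample AUCs
#'
#' @param object A `pr_auc` from [crossval_evaluate()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pr_auc <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 40, fill = "#2c5f8a", colour = "white") +
    ggplot2::geom_vline(xintercept = object$median_auc, linetype = "dashed") +
    ggplot2::labs(x = "test-half AUC", y = "replicates",
                  title = paste0("'", object$model, "': median AUC ",
                                 sprintf("%.3f", object$median_auc))) +
    ggplot2::theme_minimal()
}

#' ROC curves or paired AUC distributions of a model comparison
#'
#' @param object A `pr_comparison` from [compare_models()].
#' @param type `"roc"` (curves, one facet per rendering when both were
#'   computed) or `"auc"` (per-replicate AUC distributions).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pr_comparison <- function(object, type = c("roc", "auc"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    if (is.null(object$roc)) {
      stop("comparison was run with roc = \"none\"", call. = FALSE)
    }
    p <- ggplot2::ggplot(object$roc,
                         ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                      colour = .data$model)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey80") +
      ggplot2::geom_path() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                    title = "Out-of-sample ROC") +
      ggplot2::theme_minimal()
    if (length(unique(object$roc$rendering)) > 1) {
      p <- p + ggplot2::facet_wrap(~rendering)
    }
    return(p)
  }
  ggplot2::ggplot(object$aucs,
                  ggplot2::aes(x = .data$auc, fill = .data$model)) +
    ggplot2::geom_density(alpha = 0.4, colour = NA) +
    ggplot2::labs(x = "test-half AUC", y = "density",
                  title = "Per-replicate AUC across shared splits") +
    ggplot2::theme_minimal()
}
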