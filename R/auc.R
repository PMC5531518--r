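# Rank-based AUC (Mann-Whitney) and ROC curves.

#' Rank-based AUC
#'
#' The probability that a random case scores higher than a random control,
#' with ties credited 0.5 (Mann-Whitney convention):
#' `(#\{case > control\} + 0.5 #\{case = control\}) / (n_case * n_control)`.
#' Computed via midranks in O(n log n).
#'
#' @param case_scores,control_scores Numeric score vectors (both
#'   non-empty).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(3, 1), c(2, 0)) # 3 of 4 pairs concordant: 0.75
#' @export
auc_rank <- function(case_scores, control_scores) {
  m <- length(case_scores); n <- length(control_scores)
  if (m == 0 || n == 0) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Empirical ROC curve
#'
#' Ordered (false-positive rate, true-positive rate) points from (0, 0) to
#' (1, 1), one step per distinct score threshold. On tie-free scores the
#' trapezoidal area under the curve equals [auc_rank()].
#'
#' @param case_scores,control_scores Numeric score vectors.
#' @return A tibble with columns `fpr`, `tpr`, both non-decreasing.
#' @export
roc_curve <- function(case_scores, control_scores) {
  m <- length(case_scores); n <- length(control_scores)
  if (m == 0 || n == 0) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  scores <- c(case_scores, control_scores)
  is_case <- rep(c(TRUE, FALSE), c(m, n))
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_case[ord])
  fp <- cumsum(!is_case[ord])
  # collapse tied thresholds: keep the last point of each score value
  last <- rev(!duplicated(rev(scores[ord])))
  tibble(fpr = c(0, fp[last] / n), tpr = c(0, tp[last] / m))
}

#' Trapezoidal area under a ROC curve
#' @param roc A tibble from [roc_curve()].
#' @return The trapezoidal area.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}
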