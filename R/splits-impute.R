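# Random equal-size train/test splits and hot-deck imputation from control
# donor pools. Replicate seeds follow a documented schedule,
# seed_i = master XOR i, so replicates are reproducible, order-independent
# and prefix-consistent when the replicate count changes, and so the
# ensemble and every compared model share the same split/imputation draws.

#' Replicate seed schedule
#'
#' `replicate_seed(master, i) = bitwXor(master, i)`. Every randomized stage
#' of replicate `i` (imputation, then splitting) runs under this seed.
#'
#' @param master_seed Non-negative integer master seed.
#' @param index Replicate index (1-based).
#' @return Integer seed.
#' @export
replicate_seed <- function(master_seed, index) {
  bitwXor(as.integer(master_seed), as.integer(index))
}

#' Random equal-size train/test split
#'
#' Uniformly random partition of the samples into halves. With an odd
#' number of samples the training half receives the extra sample. The
#' split is not stratified by case status unless `stratify = TRUE`, in
#' which case cases and controls are halved separately.
#'
#' @param cohort A `pr_cohort`.
#' @param seed Optional seed (`NULL` uses the current RNG state).
#' @param stratify Stratify the split by case status.
#' @param replicate_index Bookkeeping index carried into the result.
#' @return A `pr_split`: list with `train_ids`, `test_ids`, `seed`,
#'   `replicate_index`.
#' @export
random_split <- function(cohort, seed = NULL, stratify = FALSE,
                         replicate_index = NA_integer_) {
  stopifnot(inherits(cohort, "pr_cohort"))
  ids <- cohort$data$sample_id
  if (length(ids) < 2) stop("cannot split fewer than 2 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (stratify) {
    case_ids <- ids[cohort$data$status == 1]
    ctrl_ids <- ids[cohort$data$status == 0]
    tr <- c(sample(case_ids, ceiling(length(case_ids) / 2)),
            sample(ctrl_ids, ceiling(length(ctrl_ids) / 2)))
  } else {
    tr <- sample(ids, ceiling(length(ids) / 2))
  }
  structure(list(train_ids = tr, test_ids = setdiff(ids, tr),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 replicate_index = replicate_index),
            class = "pr_split")
}

#' @export
print.pr_split <- function(x, ...) {
  cat("<pr_split> train ", length(x$train_ids), " / test ",
      length(x$test_ids), " samples\n", sep = "")
  invisible(x)
}

#' Hot-deck imputation from control donor pools
#'
#' Every missing cell (in cases and controls alike) is replaced by a value
#' drawn uniformly at random, with replacement, from the non-missing
#' *control* values of the same variable. Observed cells and case/control
#' labels are never altered; imputed values are always members of the donor
#' pool.
#'
#' @param cohort A `pr_cohort`.
#' @param seed Optional seed (`NULL` uses the current RNG state).
#' @param donor_ids Optional sample-id subset restricting the donor pool
#'   (e.g. training-half controls for the strict leakage-free mode); only
#'   controls among them donate.
#' @return A complete `pr_cohort`.
#' @export
hot_deck_impute <- function(cohort, seed = NULL, donor_ids = NULL) {
  stopifnot(inherits(cohort, "pr_cohort"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  data <- cohort$data
  donors <- data$status == 0
  if (!is.null(donor_ids)) donors <- donors & data$sample_id %in% donor_ids
  for (v in cohort$meta$name) {
    x <- data[[v]]
    miss <- which(is.na(x))
    if (length(miss) == 0) next
    pool <- x[donors & !is.na(x)]
    if (length(pool) == 0) {
      stop("empty hot-deck donor pool for variable '", v, "'", call. = FALSE)
    }
    x[miss] <- pool[sample.int(length(pool), length(miss), replace = TRUE)]
    data[[v]] <- x
  }
  cohort$data <- data
  cohort
}

# One replicate's randomized preprocessing. Default donor mode imputes the
# full cohort from all observed control values before splitting (the most
# literal reading of the emulated procedure; the minor train/test leakage
# is documented). Strict mode splits first and restricts donors to
# training-half controls.
replicate_data <- function(cohort, rep_seed,
                           donor_mode = c("all_controls", "train_controls"),
                           stratify = FALSE, replicate_index = NA_integer_) {
  donor_mode <- match.arg(donor_mode)
  set.seed(as.integer(rep_seed))
  if (donor_mode == "all_controls") {
    imputed <- hot_deck_impute(cohort)
    split <- random_split(imputed, stratify = stratify,
                          replicate_index = replicate_index)
  } else {
    split <- random_split(cohort, stratify = stratify,
                          replicate_index = replicate_index)
    imputed <- hot_deck_impute(cohort, donor_ids = split$train_ids)
  }
  split$seed <- as.integer(rep_seed)
  list(imputed = imputed, split = split)
}
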