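# Cohort container: a samples x variables table with case/control status,
# plus per-variable metadata. Missing values are NA in the data tibble.

#' Describe the variables of a cohort
#'
#' Builds the per-variable metadata table that accompanies a cohort:
#' each variable is a `genotype` (additive effect-allele count 0/1/2),
#' a `binary` indicator (0/1) or a `continuous` measurement.
#'
#' @param name Character vector of variable names (unique within a cohort).
#' @param kind One of `"genotype"`, `"binary"`, `"continuous"` (recycled).
#' @param effect_allele Effect allele symbol (`A`/`C`/`G`/`T` or `I`/`D` for
#'   insertion/deletion). Required for genotype variables, must be `NA`
#'   otherwise: the coded value 0/1/2 counts copies of this allele.
#' @param gene_label Optional free-text gene annotation.
#' @return A tibble with columns `name`, `kind`, `effect_allele`, `gene_label`.
#' @examples
#' variable_meta(c("rs6025", "smoking"), c("genotype", "binary"),
#'               effect_allele = c("A", NA))
#' @export
variable_meta <- function(name, kind,
                          effect_allele = NA_character_,
                          gene_label = NA_character_) {
  meta <- tibble(
    name = as.character(name),
    kind = as.character(kind),
    effect_allele = as.character(effect_allele),
    gene_label = as.character(gene_label)
  )
  bad_kind <- setdiff(unique(meta$kind), c("genotype", "binary", "continuous"))
  if (length(bad_kind) > 0) {
    stop("unknown variable kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$name)) {
    stop("duplicate variable name(s): ",
         paste(unique(meta$name[duplicated(meta$name)]), collapse = ", "),
         call. = FALSE)
  }
  geno <- meta$kind == "genotype"
  if (any(geno & is.na(meta$effect_allele))) {
    stop("genotype variables need an effect_allele: ",
         paste(meta$name[geno & is.na(meta$effect_allele)], collapse = ", "),
         call. = FALSE)
  }
  if (any(!geno & !is.na(meta$effect_allele))) {
    stop("effect_allele is only meaningful for genotype variables",
         call. = FALSE)
  }
  meta
}

#' Assemble a case-control cohort
#'
#' Bundles a data tibble (one row per sample) with its variable metadata and
#' checks the value contracts: unique sample identifiers, status coded
#' 1 = case / 0 = control, genotypes in {0, 1, 2} and binaries in {0, 1}
#' where observed. `NA` marks a missing value; status is never missing.
#'
#' @param data A data frame with columns `sample_id`, `status`, and one
#'   column per metadata variable.
#' @param meta A metadata tibble from [variable_meta()].
#' @return An object of class `pr_cohort` (a list with elements `data`,
#'   a tibble, and `meta`).
#' @seealso [validate_cohort()] for the non-erroring report, and
#'   [read_cohort_csv()] for the file reader.
#' @export
cohort <- function(data, meta) {
  data <- as_tibble(data)
  required <- c("sample_id", "status", meta$name)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[required]
  data$sample_id <- as.character(data$sample_id)
  dup <- unique(data$sample_id[duplicated(data$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data$status) || !all(data$status %in% c(0, 1))) {
    bad <- which(is.na(data$status) | !data$status %in% c(0, 1))
    stop("status must be 0 (control) or 1 (case); offending row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  data$status <- as.integer(data$status)
  for (i in seq_len(nrow(meta))) {
    v <- meta$name[i]
    x <- data[[v]]
    if (!is.numeric(x)) {
      stop("column '", v, "' must be numeric", call. = FALSE)
    }
    allowed <- switch(meta$kind[i], genotype = c(0, 1, 2), binary = c(0, 1),
                      continuous = NULL)
    if (!is.null(allowed)) {
      bad <- which(!is.na(x) & !x %in% allowed)
      if (length(bad) > 0) {
        stop("column '", v, "' (", meta$kind[i], ") has invalid value ",
             x[bad[1]], " in row ", bad[1], call. = FALSE)
      }
    }
  }
  structure(list(data = data, meta = meta), class = "pr_cohort")
}

#' @export
print.pr_cohort <- function(x, ...) {
  n <- nrow(x$data)
  n_case <- sum(x$data$status == 1)
  kinds <- table(factor(x$meta$kind, c("genotype", "binary", "continuous")))
  vals <- x$data[x$meta$name]
  n_miss <- sum(is.na(vals))
  cat("<pr_cohort> ", n_case, " cases / ", n - n_case, " controls; ",
      nrow(x$meta), " variables (", kinds[["genotype"]], " genotype, ",
      kinds[["binary"]], " binary, ", kinds[["continuous"]], " continuous); ",
      n_miss, " missing cells (",
      sprintf("%.1f%%", 100 * n_miss / max(1, n * nrow(x$meta))), ")\n",
      sep = "")
  invisible(x)
}

#' Number of samples, cases and controls in a cohort
#' @param cohort A `pr_cohort`.
#' @return A one-row tibble with `n`, `n_cases`, `n_controls`, `n_variables`.
#' @export
cohort_sizes <- function(cohort) {
  stopifnot(inherits(cohort, "pr_cohort"))
  tibble(n = nrow(cohort$data),
         n_cases = sum(cohort$data$status == 1),
         n_controls = sum(cohort$data$status == 0),
         n_variables = nrow(cohort$meta))
}

#' Validate a cohort for the resampling pipeline
#'
#' A report-based check (never errors): flags cohorts with no cases or no
#' controls, variables missing in every sample, and variables with no
#' observed control value. The last condition breaks hot-deck imputation,
#' whose donor pools are the non-missing control values of each variable.
#'
#' @param cohort A `pr_cohort`.
#' @return A tibble of violations with columns `rule`, `variable`,
#'   `message`; zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "pr_cohort"))
  out <- list()
  add <- function(rule, variable, message) {
    out[[length(out) + 1]] <<- tibble(rule = rule, variable = variable,
                                      message = message)
  }
  status <- cohort$data$status
  if (sum(status == 1) == 0) {
    add("no_cases", NA_character_, "cohort contains no cases")
  }
  if (sum(status == 0) == 0) {
    add("no_controls", NA_character_, "cohort contains no controls")
  }
  for (v in cohort$meta$name) {
    x <- cohort$data[[v]]
    if (all(is.na(x))) {
      add("all_missing", v, paste0("'", v, "' is missing in every sample"))
    }
    if (all(is.na(x[status == 0]))) {
      add("no_control_donor_pool", v,
          paste0("'", v, "' has no observed control value ",
                 "(empty hot-deck donor pool)"))
    }
  }
  if (length(out) == 0) {
    return(tibble(rule = character(), variable = character(),
                  message = character()))
  }
  dplyr::bind_rows(out)
}

#' Read a cohort from CSV
#'
#' Expects a header `sample_id,status,<var>,...` with one row per sample.
#' Empty fields and the token `NA` are read as missing. Value contracts
#' (status coding, genotype range, unique identifiers) are enforced as in
#' [cohort()].
#'
#' @param path Path to a CSV file.
#' @param meta Variable metadata from [variable_meta()]; every metadata
#'   variable must be present in the header.
#' @return A `pr_cohort`.
#' @export
read_cohort_csv <- function(path, meta) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(c("sample_id", "status", meta$name), hdr)
  if (length(missing_cols) > 0) {
    stop("cohort file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  types <- do.call(readr::cols, c(
    list(sample_id = readr::col_character(), .default = readr::col_skip()),
    c(list(status = readr::col_double()),
      setNames(rep(list(readr::col_double()), nrow(meta)), meta$name))
  ))
  data <- readr::read_csv(path, col_types = types, na = c("", "NA"))
  cohort(data, meta)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: missing cells are written as `NA`, and
#' a read of the written file reproduces every observed value and the
#' missing mask exactly.
#'
#' @param cohort A `pr_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "pr_cohort"))
  readr::write_csv(cohort$data, path, na = "NA")
  invisible(path)
}
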