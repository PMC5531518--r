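# Model specifications: a named variable set, optionally with fixed
# coefficients. refit = TRUE models are re-estimated on every training
# half; refit = FALSE models are applied with their coefficients as-is
# (literature scores such as clinician-practice algorithms).

#' Specify a risk model
#'
#' @param name Model name.
#' @param variables Character vector of variable names (order preserved).
#' @param coefficients Optional named or positional numeric vector of
#'   log-odds coefficients, one per variable. Required when `refit = FALSE`.
#' @param intercept Optional intercept on the log-odds scale. Needed to emit
#'   calibrated probabilities; irrelevant to AUC.
#' @param refit If `TRUE` (default) the model's coefficients are re-estimated
#'   on each training set; if `FALSE` the fixed coefficients are used as-is.
#' @param se,selection_frequency Optional per-variable annotations (carried
#'   through JSON round-trips; not used for scoring).
#' @return An object of class `pr_model_spec`.
#' @examples
#' model_spec("dehaan5",
#'            c("rs6025", "rs1799963", "rs8176719", "rs2066865", "rs2036914"))
#' @export
model_spec <- function(name, variables, coefficients = NULL, intercept = NULL,
                       refit = TRUE, se = NULL, selection_frequency = NULL) {
  variables <- as.character(variables)
  if (anyDuplicated(variables)) {
    stop("duplicate variable in model '", name, "'", call. = FALSE)
  }
  align <- function(x) {
    if (is.null(x)) return(rep(NA_real_, length(variables)))
    if (!is.null(names(x)) && all(variables %in% names(x))) {
      return(as.numeric(x[variables]))
    }
    if (length(x) != length(variables)) {
      stop("length mismatch between variables and per-variable values",
           call. = FALSE)
    }
    as.numeric(x)
  }
  tbl <- tibble(name = variables,
                coefficient = align(coefficients),
                se = align(se),
                selection_frequency = align(selection_frequency))
  if (!refit && anyNA(tbl$coefficient)) {
    stop("refit = FALSE model '", name, "' lacks coefficient(s) for: ",
         paste(tbl$name[is.na(tbl$coefficient)], collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = as.character(name), refit = isTRUE(refit),
                 intercept = if (is.null(intercept)) NULL
                             else as.numeric(intercept),
                 variables = tbl),
            class = "pr_model_spec")
}

#' @export
print.pr_model_spec <- function(x, ...) {
  cat("<pr_model_spec> '", x$name, "': ", nrow(x$variables), " variables, ",
      if (x$refit) "refit per training set" else "fixed coefficients",
      if (!is.null(x$intercept)) paste0(", intercept ", signif(x$intercept, 4))
      else "", "\n", sep = "")
  invisible(x)
}

#' Built-in comparison model registry
#'
#' Fixed variable sets used in the model-comparison harness, all refit on
#' each training half:
#' * `clinical4` — age, BMI, smoking, family history of VTE.
#' * `genetic9` — the nine-SNP VTE panel (F5 Leiden rs6025, prothrombin
#'   rs1799963, ABO rs8176719/rs8176750, F11 rs2289252, CYP2C9 rs1799853,
#'   PROCR rs9574, SUGCT rs4379368, KNG1 rs710446).
#' * `combined13` — the union of the two sets above.
#' * `dehaan5` — published five-SNP score: rs6025, rs1799963, rs8176719,
#'   rs2066865, rs2036914.
#' * `bruzelius6` — published score reduced to six main-effect SNPs:
#'   rs6025, rs1799963, rs8176719, rs2289252, rs710446, rs2066865.
#'
#' @param name One of the registry names above.
#' @return A `pr_model_spec` with `refit = TRUE`.
#' @export
registry_model <- function(name) {
  genetic9 <- c("rs6025", "rs1799963", "rs8176719", "rs2289252", "rs1799853",
                "rs9574", "rs8176750", "rs4379368", "rs710446")
  clinical4 <- c("age", "bmi", "smoking", "family_history")
  vars <- switch(name,
    clinical4 = clinical4,
    genetic9 = genetic9,
    combined13 = c(clinical4, genetic9),
    dehaan5 = c("rs6025", "rs1799963", "rs8176719", "rs2066865", "rs2036914"),
    bruzelius6 = c("rs6025", "rs1799963", "rs8176719", "rs2289252",
                   "rs710446", "rs2066865"),
    stop("unknown registry model '", name, "'; available: ",
         paste(registry_models(), collapse = ", "), call. = FALSE)
  )
  model_spec(name, vars, refit = TRUE)
}

#' @rdname registry_model
#' @export
registry_models <- function() {
  c("clinical4", "genetic9", "combined13", "dehaan5", "bruzelius6")
}

#' Write / read a model specification as JSON
#'
#' The JSON layout is
#' `{"name", "refit", "intercept", "variables": [{"name", "coefficient",
#' "se", "selection_frequency"}, ...]}` with `null` for absent values.
#' Round-trips are lossless field-by-field. An aggregated ensemble
#' ([aggregate_ensemble()]) is serialised via [as_model_spec()].
#'
#' @param model A `pr_model_spec` or `pr_ensemble`.
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `pr_model_spec`.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "pr_ensemble")) model <- as_model_spec(model)
  stopifnot(inherits(model, "pr_model_spec"))
  num_or_null <- function(x) if (is.na(x)) NULL else x
  obj <- list(
    name = model$name,
    refit = model$refit,
    intercept = model$intercept,
    variables = purrr::pmap(model$variables, function(name, coefficient, se,
                                                      selection_frequency) {
      list(name = name, coefficient = num_or_null(coefficient),
           se = num_or_null(se),
           selection_frequency = num_or_null(selection_frequency))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed model JSON '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(obj$name) || is.null(obj$variables)) {
    stop("malformed model JSON '", path, "': needs 'name' and 'variables'",
         call. = FALSE)
  }
  grab <- function(field) {
    purrr::map_dbl(obj$variables, ~ .x[[field]] %||% NA_real_)
  }
  model_spec(
    name = obj$name,
    variables = purrr::map_chr(obj$variables, "name"),
    coefficients = grab("coefficient"),
    se = grab("se"),
    selection_frequency = grab("selection_frequency"),
    intercept = obj$intercept,
    refit = isTRUE(obj$refit)
  )
}

#' Convert an aggregated ensemble to a model specification
#'
#' The final model consists of the variables with non-zero median
#' coefficient; the median intercept is carried over so the model can emit
#' calibrated probabilities.
#'
#' @param x A `pr_ensemble`.
#' @param name Model name for the spec.
#' @param refit If `FALSE` (default) the median coefficients are kept as
#'   fixed coefficients; if `TRUE` only the variable set is kept.
#' @param keep_zero Keep variables whose median coefficient is zero.
#' @return A `pr_model_spec`.
#' @export
as_model_spec <- function(x, name = NULL, refit = FALSE, keep_zero = FALSE) {
  UseMethod("as_model_spec")
}

#' @export
as_model_spec.pr_model_spec <- function(x, name = NULL, refit = NULL,
                                        keep_zero = FALSE) {
  if (!is.null(name)) x$name <- name
  if (!is.null(refit)) x$refit <- isTRUE(refit)
  x
}

#' @export
as_model_spec.pr_ensemble <- function(x, name = "ensemble", refit = FALSE,
                                      keep_zero = FALSE) {
  tbl <- x$table
  if (!keep_zero) tbl <- tbl[tbl$median_coefficient != 0, ]
  model_spec(name, tbl$variable,
             coefficients = tbl$median_coefficient,
             se = tbl$median_se,
             selection_frequency = tbl$selection_frequency,
             intercept = x$intercept, refit = refit)
}
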