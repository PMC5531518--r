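# Optional genotype import from VCF, via vcfR. GT fields are converted to
# effect-allele counts; half-calls and fully missing calls become NA.

#' Import genotypes from a VCF file
#'
#' Converts GT fields to additive effect-allele counts. For each requested
#' variant the effect allele must be the REF or one of the ALT alleles;
#' its dosage (0/1/2) is counted across the two call alleles. Calls with
#' any missing allele (`./.`, `.|.`, half-calls like `./1`) become `NA`.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param effect_alleles Named character vector mapping variant ID (the VCF
#'   `ID` column) to its effect allele sequence; variants absent from the
#'   map are skipped.
#' @return A tibble with `sample_id` and one 0/1/2 column per variant,
#'   suitable for binding into [cohort()] data.
#' @export
read_genotypes_vcf <- function(path, effect_alleles) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required for VCF import", call. = FALSE)
  }
  stopifnot(is.character(effect_alleles), !is.null(names(effect_alleles)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  keep <- which(ids %in% names(effect_alleles))
  if (length(keep) == 0) {
    stop("none of the requested variants are present in ", path,
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- tibble(sample_id = colnames(gt))
  for (i in keep) {
    id <- ids[i]
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",")[[1]])
    eff_idx <- match(effect_alleles[[id]], alleles) - 1L # VCF allele index
    if (is.na(eff_idx)) {
      stop("effect allele '", effect_alleles[[id]], "' of ", id,
           " is neither REF nor ALT in the VCF", call. = FALSE)
    }
    calls <- strsplit(gt[i, ], "[/|]")
    out[[id]] <- unname(vapply(calls, function(a) {
      if (length(a) != 2 || anyNA(a) || any(a == ".")) return(NA_real_)
      sum(a == as.character(eff_idx))
    }, numeric(1)))
  }
  out
}
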