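# Shared fixture builders. Everything is generated in code; no data files.

tiny_meta <- function() {
  variable_meta(c("rs0001", "smoking", "bmi"),
                c("genotype", "binary", "continuous"),
                effect_allele = c("A", NA, NA))
}

# 8 samples, one variable of each kind, a few missing cells
tiny_cohort <- function() {
  cohort(
    tibble::tibble(
      sample_id = sprintf("S%d", 1:8),
      status = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
      rs0001 = c(0, 1, 2, NA, 0, 0, 1, 2),
      smoking = c(1, 0, NA, 1, 0, 1, 0, 0),
      bmi = c(24.5, 31, 22, 27, NA, 21.5, 23, 25)
    ),
    tiny_meta()
  )
}

# binary cohort with exact per-group positive counts (for percentage checks)
counts_cohort <- function(case_pos, case_n, ctrl_pos, ctrl_n,
                          var = "flag", ctrl_missing = 0) {
  x_case <- rep(c(1, 0), c(case_pos, case_n - case_pos))
  x_ctrl <- c(rep(c(1, 0), c(ctrl_pos, ctrl_n - ctrl_pos)),
              rep(NA, ctrl_missing))
  dat <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(case_n + ctrl_n + ctrl_missing)),
    status = rep(c(1L, 0L), c(case_n, ctrl_n + ctrl_missing)))
  dat[[var]] <- c(x_case, x_ctrl)
  cohort(dat, variable_meta(var, "binary"))
}

# small cohort with genuine genetic + clinical signal
signal_cohort <- function(n_cases = 300, n_controls = 300, n_decoys = 2,
                          seed = 42) {
  panel <- study_panel(n_decoys = n_decoys)
  generate_cohort(panel$variants, panel$clinicals, n_cases = n_cases,
                  n_controls = n_controls, seed = seed)
}

expect_strictly_decreasing <- function(x) {
  expect_true(all(diff(x) < 0))
}
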