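test_that("degenerate frequencies and determinism behave as specified", {
  v <- variant_spec("mono", 0, true_or = 2)
  gen <- generate_cohort(v, NULL, n_cases = 20, n_controls = 20, seed = 3,
                         baseline_logit = 0)
  expect_true(all(gen$cohort$data$mono == 0))

  panel <- study_panel(n_decoys = 3)
  a <- generate_cohort(panel$variants, panel$clinicals, 60, 60, seed = 9)
  b <- generate_cohort(panel$variants, panel$clinicals, 60, 60, seed = 9)
  expect_identical(a$cohort$data, b$cohort$data)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a$cohort, pa)
  write_cohort_csv(b$cohort, pb)
  expect_identical(readLines(pa), readLines(pb))
  d <- generate_cohort(panel$variants, panel$clinicals, 60, 60, seed = 10)
  expect_false(identical(a$cohort$data, d$cohort$data))
})

test_that("genotypes follow Hardy-Weinberg proportions and decoys match their frequency", {
  v <- variant_spec("hwe", 0.5, true_or = 1)
  gen <- generate_cohort(v, NULL, n_cases = 50, n_controls = 4000, seed = 5,
                         baseline_logit = qlogis(0.02))
  g <- gen$cohort$data$hwe[gen$cohort$data$status == 0]
  obs <- tabulate(g + 1, 3)
  gof <- chisq.test(obs, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)

  v2 <- variant_spec("decoy", 0.3, true_or = 1)
  gen2 <- generate_cohort(v2, NULL, n_cases = 50, n_controls = 4000,
                          seed = 6, baseline_logit = qlogis(0.02))
  f <- allele_frequency(gen2$cohort, "decoy", "controls")
  se <- sqrt(0.3 * 0.7 / f$n_alleles)
  expect_lt(abs(f$freq - 0.3), 4 * se)
})

test_that("a null generating model yields an uninformative true linear predictor", {
  v <- variant_spec(c("n1", "n2"), c(0.3, 0.4), true_or = 1)
  gen <- generate_cohort(v, NULL, n_cases = 1000, n_controls = 1000,
                         seed = 11, baseline_logit = qlogis(0.3))
  lp <- drop(as.matrix(gen$cohort$data[c("n1", "n2")]) %*%
               gen$truth$variables$true_log_or[1:2])
  a <- auc_rank(lp[gen$cohort$data$status == 1],
                lp[gen$cohort$data$status == 0])
  expect_lt(abs(a - 0.5), 0.035)
})

test_that("case-control sampling enriches a strong variant as the sampling model predicts", {
  # independent oracle: exact case/control allele frequencies by summing the
  # three-genotype sampling model P(g) * P(status | g)
  freq <- 0.02; or <- 6.46; b <- qlogis(0.01)
  pg <- dbinom(0:2, 2, freq)
  pcase_g <- plogis(b + log(or) * (0:2))
  exp_case_freq <- sum(pg * pcase_g * (0:2)) / (2 * sum(pg * pcase_g))
  exp_ctrl_freq <- sum(pg * (1 - pcase_g) * (0:2)) /
    (2 * sum(pg * (1 - pcase_g)))
  expect_gt(exp_case_freq, 2 * freq) # strong enrichment in cases

  v <- variant_spec("rs_strong", freq, true_or = or)
  gen <- generate_cohort(v, NULL, n_cases = 3000, n_controls = 3000,
                         seed = 13, baseline_logit = b)
  f_case <- allele_frequency(gen$cohort, "rs_strong", "cases")
  f_ctrl <- allele_frequency(gen$cohort, "rs_strong", "controls")
  se_case <- sqrt(exp_case_freq * (1 - exp_case_freq) / f_case$n_alleles)
  se_ctrl <- sqrt(exp_ctrl_freq * (1 - exp_ctrl_freq) / f_ctrl$n_alleles)
  expect_lt(abs(f_case$freq - exp_case_freq), 4 * se_case)
  expect_lt(abs(f_ctrl$freq - exp_ctrl_freq), 4 * se_ctrl)
  expect_gt(f_case$freq, f_ctrl$freq)
})

test_that("a full-data logistic fit recovers the generating coefficients", {
  # coverage: fitted coefficients within 3 SE of truth for >= 95% of seeds
  panel <- study_panel(n_decoys = 0)
  vars <- c(panel$variants$name, panel$clinicals$name)
  truth <- c(panel$variants$true_log_or, panel$clinicals$true_log_or)
  n_seeds <- 100
  covered <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    gen <- generate_cohort(panel$variants, panel$clinicals, 400, 400,
                           seed = 1000 + s, target_prevalence = 0.05)
    f <- fit_logistic(as.matrix(gen$cohort$data[vars]),
                      gen$cohort$data$status)
    est <- f$coefficients[vars]
    se <- f$se[vars]
    covered[s] <- all(abs(est - truth) < 3 * se)
  }
  expect_gte(mean(covered), 0.95)
})

test_that("missingness masking is exact, MCAR-rated, and never touches status", {
  gen <- signal_cohort(40, 60, n_decoys = 1, seed = 21)
  co <- gen$cohort

  expect_identical(apply_missingness(co, mcar_rate = 0)$data, co$data)

  masks <- study_missingness(co, n_masked_controls = 30)
  masked <- apply_missingness(co, masks = masks, seed = 1)
  masked_ids <- masks[[1]]$samples
  expect_length(masked_ids, 30)
  for (v in masks[[1]]$variables) {
    expect_true(all(is.na(
      masked$data[[v]][masked$data$sample_id %in% masked_ids])))
    untouched <- !masked$data$sample_id %in% masked_ids
    expect_identical(masked$data[[v]][untouched], co$data[[v]][untouched])
  }
  expect_identical(masked$data$status, co$data$status)

  all_gone <- apply_missingness(co, mcar_rate = 1, seed = 2)
  expect_true(all(is.na(as.matrix(all_gone$data[co$meta$name]))))
  expect_identical(all_gone$data$status, co$data$status)

  expect_error(
    apply_missingness(co, masks = list(list(samples = "ghost",
                                            variables = "bmi"))),
    "unknown sample")
  expect_error(
    apply_missingness(co, masks = list(list(samples = co$data$sample_id[1],
                                            variables = "ghost_var"))),
    "unknown variable")
})

test_that("truth records round-trip through JSON", {
  gen <- signal_cohort(30, 30, seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(gen$truth, path)
  back <- read_truth_json(path)
  expect_equal(back$variables$true_log_or, gen$truth$variables$true_log_or)
  expect_equal(back$intercept, gen$truth$intercept)
  expect_equal(back$seed, gen$truth$seed)
})
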