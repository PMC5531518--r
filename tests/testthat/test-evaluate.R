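auc_enumerate <- function(cases, controls) {
  tot <- 0
  for (x in cases) for (y in controls) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(cases) * length(controls))
}

test_that("rank AUC matches its definition on worked examples", {
  expect_equal(auc_rank(c(2, 3), c(0, 1)), 1)
  expect_equal(auc_rank(rep(1, 5), rep(1, 7)), 0.5)
  expect_equal(auc_rank(c(3, 1), c(2, 0)), 0.75)
  expect_error(auc_rank(numeric(0), 1), "non-empty")
})

test_that("rank AUC equals exhaustive pair enumeration on random score sets", {
  set.seed(101)
  for (i in 1:50) {
    m <- sample(1:20, 1); n <- sample(1:20, 1)
    cases <- sample(0:10, m, replace = TRUE) # ties likely
    controls <- sample(0:10, n, replace = TRUE)
    expect_equal(auc_rank(cases, controls),
                 auc_enumerate(cases, controls))
  }
})

test_that("AUC symmetry and monotone-transform invariance hold", {
  set.seed(102)
  for (i in 1:20) {
    cases <- rnorm(15); controls <- rnorm(12)
    a <- auc_rank(cases, controls)
    expect_equal(a + auc_rank(controls, cases), 1)
    expect_equal(auc_rank(exp(2 * cases + 1), exp(2 * controls + 1)), a)
  }
})

test_that("trapezoidal ROC area equals the rank AUC on tie-free scores", {
  set.seed(103)
  for (i in 1:200) {
    cases <- rnorm(sample(2:15, 1))
    controls <- rnorm(sample(2:15, 1))
    rc <- roc_curve(cases, controls)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(rc$fpr[1], 0)
    expect_equal(rc$tpr[nrow(rc)], 1)
    expect_equal(roc_auc(rc), auc_rank(cases, controls), tolerance = 1e-12)
  }
})

test_that("cross-validated AUC is ~0.5 for null models and reproducible", {
  v <- variant_spec(c("n1", "n2"), c(0.3, 0.4), true_or = 1)
  gen <- generate_cohort(v, NULL, n_cases = 200, n_controls = 200,
                         seed = 71, baseline_logit = qlogis(0.3))
  res <- crossval_evaluate(gen$cohort, model_spec("null", c("n1", "n2")),
                           n_replicates = 40, master_seed = 4)
  expect_lt(abs(res$median_auc - 0.5), 0.06)
  again <- crossval_evaluate(gen$cohort, model_spec("null", c("n1", "n2")),
                             n_replicates = 40, master_seed = 4)
  expect_identical(res$aucs, again$aucs)
})

test_that("a single-SNP refit model approaches the enumerated genotype AUC", {
  freq <- 0.3; or <- 3; b <- qlogis(0.05)
  v <- variant_spec("g", freq, true_or = or)
  gen <- generate_cohort(v, NULL, n_cases = 800, n_controls = 800,
                         seed = 73, baseline_logit = b)
  # oracle: AUC of the genotype score from the exact sampling distribution
  pg <- dbinom(0:2, 2, freq)
  pcase_g <- plogis(b + log(or) * (0:2))
  p_case <- pg * pcase_g / sum(pg * pcase_g)
  p_ctrl <- pg * (1 - pcase_g) / sum(pg * (1 - pcase_g))
  oracle <- 0
  for (gc in 0:2) for (gn in 0:2) {
    oracle <- oracle + p_case[gc + 1] * p_ctrl[gn + 1] *
      ((gc > gn) + 0.5 * (gc == gn))
  }
  res <- crossval_evaluate(gen$cohort, model_spec("one", "g"),
                           n_replicates = 30, master_seed = 5)
  expect_gt(res$median_auc, 0.5)
  expect_lt(abs(res$median_auc - oracle), 0.03)
})

test_that("fixed-coefficient models are applied as-is", {
  gen <- signal_cohort(150, 150, n_decoys = 0, seed = 75)
  fixed <- model_spec("fixed", c("rs6025", "bmi"),
                      coefficients = c(log(6.46), log(1.07)),
                      intercept = -5, refit = FALSE)
  res <- crossval_evaluate(gen$cohort, fixed, n_replicates = 20,
                           master_seed = 6)
  expect_gt(res$median_auc, 0.5)
  expect_error(model_spec("bad", c("a"), refit = FALSE), "coefficient")
})

test_that("model comparison shares splits: identical specs tie exactly", {
  gen <- signal_cohort(120, 120, n_decoys = 0, seed = 77)
  cmp <- compare_models(
    gen$cohort,
    list(a = model_spec("a", c("rs6025", "bmi")),
         b = model_spec("b", c("rs6025", "bmi"))),
    n_replicates = 15, master_seed = 7, roc = "none")
  wide <- tidyr::pivot_wider(cmp$aucs, names_from = "model",
                             values_from = "auc")
  expect_equal(wide$a, wide$b)
})

test_that("combined models dominate their sub-models on shared splits", {
  gen <- signal_cohort(400, 400, n_decoys = 0, seed = 79)
  cmp <- compare_models(gen$cohort,
                        list("combined13", "genetic9", "clinical4"),
                        n_replicates = 60, master_seed = 8, roc = "none")
  tbl <- cmp$table
  med <- setNames(tbl$median_auc, tbl$model)
  expect_gte(med[["combined13"]], med[["genetic9"]])
  expect_gte(med[["combined13"]], med[["clinical4"]])
  # nested per-replicate differences have non-negative median
  wide <- tidyr::pivot_wider(cmp$aucs, names_from = "model",
                             values_from = "auc")
  expect_gte(median(wide$combined13 - wide$genetic9), 0)
})

test_that("comparison ROC renderings are well-formed curves", {
  gen <- signal_cohort(100, 100, n_decoys = 0, seed = 81)
  cmp <- compare_models(gen$cohort, list("genetic9"), n_replicates = 10,
                        master_seed = 9, roc = "both")
  for (rend in c("pooled", "averaged")) {
    rc <- cmp$roc[cmp$roc$rendering == rend, ]
    expect_gt(nrow(rc), 2)
    expect_true(all(diff(rc$fpr) >= 0))
    expect_true(all(rc$tpr >= 0 & rc$tpr <= 1))
  }
  expect_error(compare_models(gen$cohort, list("dehaan5"),
                              n_replicates = 2, master_seed = 1),
               "rs2066865")
})

test_that("individual scoring is linear in covariates and honors the intercept contract", {
  m <- model_spec("score", c("g", "b"), coefficients = c(log(2), 0.5),
                  intercept = -1, refit = FALSE)
  rows <- tibble::tibble(g = c(0, 2), b = c(0, 0))
  out <- score_individuals(m, rows)
  expect_equal(out$score[1], -1) # all covariates zero: the intercept
  expect_equal(out$score[2] - out$score[1], 2 * log(2))
  expect_equal(out$probability, plogis(out$score))

  no_int <- model_spec("ni", "g", coefficients = log(2), refit = FALSE)
  out2 <- score_individuals(no_int, rows)
  expect_false("probability" %in% names(out2))
  expect_true("score" %in% names(out2))

  expect_error(score_individuals(m, tibble::tibble(g = 1)), "lacks model")
  expect_error(score_individuals(m, tibble::tibble(g = NA_real_, b = 1)),
               "missing covariate")
  out3 <- score_individuals(m, tibble::tibble(g = NA_real_, b = 1),
                            on_missing = "na")
  expect_true(is.na(out3$score))
})
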