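# fabricate a replicate table the way run_ensemble() records it
fake_replicates <- function(coefs, ses, candidates) {
  tbl <- tibble::tibble(
    replicate = seq_along(coefs),
    seed = seq_along(coefs),
    n_selected = vapply(coefs, function(b) length(b) - 1L, integer(1)),
    aic = 0, skipped = 0L,
    selected = lapply(coefs, function(b) setdiff(names(b), "(Intercept)")),
    coef = coefs, se = ses)
  attr(tbl, "candidates") <- candidates
  tbl
}

test_that("a one-replicate ensemble composes impute, split and stepwise", {
  gen <- signal_cohort(120, 120, n_decoys = 1, seed = 51)
  co <- apply_missingness(gen$cohort,
                          masks = study_missingness(gen$cohort, 40),
                          seed = 52)
  reps <- run_ensemble(co, n_replicates = 1, master_seed = 77)
  expect_equal(nrow(reps), 1)

  # reproduce the replicate through the exported pieces
  rs <- replicate_seed(77, 1)
  set.seed(rs)
  imp <- hot_deck_impute(co)
  sp <- random_split(imp)
  train <- imp$data[imp$data$sample_id %in% sp$train_ids, ]
  st <- stepwise_select(train, candidates = co$meta$name)
  expect_identical(reps$selected[[1]], st$selected)
  expect_equal(reps$coef[[1]], st$fit$coefficients)
  expect_equal(reps$aic[1], st$fit$aic)
})

test_that("the ensemble is reproducible and prefix-consistent in the replicate count", {
  gen <- signal_cohort(80, 80, n_decoys = 1, seed = 53)
  a <- run_ensemble(gen$cohort, n_replicates = 8, master_seed = 5)
  b <- run_ensemble(gen$cohort, n_replicates = 8, master_seed = 5)
  expect_identical(a$selected, b$selected)
  expect_equal(a$coef, b$coef)
  short <- run_ensemble(gen$cohort, n_replicates = 4, master_seed = 5)
  expect_identical(short$selected, a$selected[1:4])
  expect_equal(short$aic, a$aic[1:4])
  other <- run_ensemble(gen$cohort, n_replicates = 4, master_seed = 6)
  expect_false(identical(other$selected, short$selected))
})

test_that("median aggregation zero-fills unselected replicates and splits SE medians", {
  cands <- c("x", "z")
  reps <- fake_replicates(
    coefs = list(c(`(Intercept)` = -1),
                 c(`(Intercept)` = -1.5, x = 0.5),
                 c(`(Intercept)` = -2, x = 1.0)),
    ses = list(c(`(Intercept)` = 0.1),
               c(`(Intercept)` = 0.1, x = 0.2),
               c(`(Intercept)` = 0.1, x = 0.4)),
    candidates = cands)
  ens <- aggregate_ensemble(reps)
  x_row <- ens$table[ens$table$variable == "x", ]
  expect_equal(x_row$median_coefficient, 0.5) # median of {0, 0.5, 1.0}
  expect_equal(x_row$median_se, 0.3) # over the two selected runs only
  expect_equal(x_row$selection_frequency, 2 / 3)
  expect_equal(ens$intercept, -1.5)

  # never selected: OR exactly 1, no SE / p / q
  z_row <- ens$table[ens$table$variable == "z", ]
  expect_identical(z_row$or, 1)
  expect_identical(z_row$median_coefficient, 0)
  expect_true(is.na(z_row$median_se) && is.na(z_row$p) && is.na(z_row$q))
})

test_that("Wald intervals reproduce a published-style CI from its own SE", {
  # SE back-derived from the printed interval 4.04-10.3 around OR 6.46
  se_bd <- (log(10.3) - log(4.04)) / (2 * 1.96)
  reps <- fake_replicates(
    coefs = list(c(`(Intercept)` = -3, rs6025 = log(6.46))),
    ses = list(c(`(Intercept)` = 0.2, rs6025 = se_bd)),
    candidates = "rs6025")
  ens <- aggregate_ensemble(reps)
  row <- ens$table[1, ]
  expect_equal(row$or, 6.46, tolerance = 1e-10)
  expect_equal(row$ci_lo, 4.04, tolerance = 0.01)
  expect_equal(row$ci_hi, 10.3, tolerance = 0.02)
})

test_that("aggregation invariants hold on a simulated ensemble", {
  gen <- signal_cohort(250, 250, n_decoys = 2, seed = 55)
  reps <- run_ensemble(gen$cohort, n_replicates = 25, master_seed = 9)
  ens <- aggregate_ensemble(reps)
  tbl <- ens$table
  # OR = 1 exactly iff the median coefficient is zero
  expect_identical(tbl$or == 1, tbl$median_coefficient == 0)
  # CI brackets the OR whenever defined
  ok <- !is.na(tbl$median_se)
  expect_true(all(tbl$ci_lo[ok] <= tbl$or[ok] & tbl$or[ok] <= tbl$ci_hi[ok]))
  # BH adjustment never decreases a p-value
  expect_true(all(tbl$q[ok] >= tbl$p[ok] - 1e-12))
  # selection frequencies recompute from the replicate records
  for (v in tbl$variable) {
    expect_equal(tbl$selection_frequency[tbl$variable == v],
                 mean(vapply(reps$selected, function(s) v %in% s,
                             logical(1))))
  }
})

test_that("study-scale ensembles recover generating coefficients and rank decoys low", {
  panel <- study_panel(n_decoys = 5)
  gen <- generate_cohort(panel$variants, panel$clinicals, seed = 57)
  reps <- run_ensemble(gen$cohort, n_replicates = 40, master_seed = 21)
  ens <- aggregate_ensemble(reps)
  tbl <- ens$table
  # back-derived SEs from the published intervals
  se_bd <- c(rs6025 = (log(10.3) - log(4.04)) / 3.92,
             rs1799963 = (log(9.31) - log(3.01)) / 3.92,
             smoking = (log(2.09) - log(1.27)) / 3.92,
             family_history = (log(2.83) - log(1.61)) / 3.92)
  truth <- c(rs6025 = log(6.46), rs1799963 = log(5.32),
             smoking = log(1.63), family_history = log(2.13))
  for (v in names(truth)) {
    est <- tbl$median_coefficient[tbl$variable == v]
    expect_lt(abs(est - truth[[v]]), 2 * se_bd[[v]])
  }
  decoy_freq <- tbl$selection_frequency[grepl("^decoy", tbl$variable)]
  strong_freq <- tbl$selection_frequency[tbl$variable %in%
                                           c("rs6025", "rs1799963")]
  expect_true(max(decoy_freq) < min(strong_freq))
})

test_that("force-include propagates through the ensemble", {
  gen <- signal_cohort(100, 100, n_decoys = 0, seed = 59)
  reps <- run_ensemble(gen$cohort, n_replicates = 5, master_seed = 3,
                       force = "age")
  expect_true(all(vapply(reps$selected, function(s) "age" %in% s,
                         logical(1))))
  ens <- aggregate_ensemble(reps)
  expect_equal(ens$table$selection_frequency[ens$table$variable == "age"], 1)
})

test_that("the ensemble report and model spec expose the final model", {
  gen <- signal_cohort(150, 150, n_decoys = 1, seed = 61)
  reps <- run_ensemble(gen$cohort, n_replicates = 10, master_seed = 2)
  ens <- aggregate_ensemble(reps)
  spec <- as_model_spec(ens, name = "final")
  expect_false(spec$refit)
  expect_setequal(spec$variables$name,
                  ens$table$variable[ens$table$median_coefficient != 0])
  expect_equal(spec$intercept, ens$intercept)
  rep_tbl <- ensemble_report(ens, gen$cohort)
  expect_true(all(rep_tbl$variable %in% spec$variables$name))
  expect_true(all(c("or", "ci_lo", "ci_hi", "q") %in% names(rep_tbl)))
})
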