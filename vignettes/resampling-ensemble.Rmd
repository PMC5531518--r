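---
title: "A resampling stepwise-AIC ensemble for VTE risk in oral contraceptive users"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A resampling stepwise-AIC ensemble for VTE risk in oral contraceptive users}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Venous thromboembolism (VTE) is rare but serious in women using combined
oral contraceptives (CC) — on the order of one event per thousand users
per year. Clinical risk factors (age, body-mass index, smoking, family
history of VTE) discriminate poorly on their own, and the two canonical
thrombophilia genotypes (factor V Leiden rs6025 and prothrombin G20210A
rs1799963) explain only a minority of the inherited risk. `pillrisk`
implements a pipeline for building and evaluating a combined
clinical-plus-genetic risk score from a case-control cohort of CC users
genotyped on a candidate SNP panel, together with a synthetic-cohort
generator that reproduces the statistical structure such a study
produces, so every stage can be tested against known ground truth.

## The model and the ensemble procedure

The base learner is additive-coded logistic regression: for covariates
$x_1, \dots, x_p$ (genotypes as effect-allele counts 0/1/2, binaries as
0/1, continuous as measured),

$$\operatorname{logit} P(\text{case} \mid x) = \beta_0 + \textstyle\sum_j \beta_j x_j,$$

fitted by iteratively reweighted least squares; $e^{\beta_j}$ is the
per-allele (or per-unit) odds ratio.

A single stepwise fit on one data set overstates its own discoveries
(the winner's curse). The pipeline instead repeats, a large number of
times (10,000 in the design it emulates; `n_replicates` is
configurable):

1. **Hot-deck imputation.** Every missing cell is replaced by a random
   draw, with replacement, from the non-missing *control* values of the
   same variable. Control donor pools avoid re-importing case-control
   signal into imputed cells.
2. **Random half split** into a training and a test set of equal size
   (train gets the extra sample when $n$ is odd). Splits are not
   stratified by status by default; a `stratify` flag exists.
3. **Stepwise-AIC selection** on the training half: greedy bidirectional
   search from the intercept-only model, scoring every single-variable
   addition and deletion by the AIC of its refit and moving only while
   the AIC strictly improves.
4. **Out-of-sample evaluation**: the selected (or any competing) model
   scores the test half, summarised by the rank-based AUC — the
   probability that a random case outranks a random control, ties
   credited one half.

The replicate models are then **aggregated by medians**: a variable
unselected in a replicate contributes a coefficient of exactly zero
(odds ratio 1) to its median over *all* replicates, while its standard
error is the median over the replicates where it *was* selected.
Variables with non-zero median coefficient form the final model; Wald
95% intervals and two-sided p-values follow from the median coefficient
and median SE, with Benjamini–Hochberg control at 5% FDR across all
candidates. The final AUC of any model is its median test-half AUC
across replicates, with a 2.5/97.5 percentile interval — the only
interval construction the replicate design itself supports.

Compared models (built-in registry: the 5-SNP and 6-SNP published
genetic scores, the 9-SNP genetic-only, 4-variable clinical-only and
13-variable combined sets, plus user-supplied fixed-coefficient
clinician-practice scores via `refit = FALSE` specs) are evaluated on
the *same* sequence of imputations and splits, so AUC differences are
paired and the shared Monte-Carlo noise cancels.

## A worked run

```{r}
library(pillrisk)

panel <- study_panel(n_decoys = 10)
gen <- generate_cohort(panel$variants, panel$clinicals, seed = 101)
co <- apply_missingness(gen$cohort, masks = study_missingness(gen$cohort),
                        seed = 102)

replicates <- run_ensemble(co, n_replicates = 1000, master_seed = 1)
ensemble <- aggregate_ensemble(replicates)
tidy(ensemble)
autoplot(ensemble)

cmp <- compare_models(co, list("combined13", "genetic9", "clinical4"),
                      n_replicates = 1000, master_seed = 1)
glance(cmp)
autoplot(cmp)
```

## What the synthetic generator emulates — and what it does not

`generate_cohort()` simulates population individuals and accepts them by
disease status until the case and control quotas fill (case-control
sampling). Under a correctly specified logistic disease model this
leaves every log odds ratio identifiable; only the intercept is a
nuisance of the sampling design, which is why the generator's intercept
is never a recovery target.

* **Genotypes** are drawn under Hardy–Weinberg equilibrium: two
  independent Bernoulli draws at the population effect-allele
  frequency. No linkage disequilibrium is simulated.
* **Clinical covariates**: age (truncated normal, mean 31.5, SD 9,
  range 18–51 years) and BMI (mean 23, SD 4.2, range 17.5–33.5
  kg/m²) redrawn until inside their bounds; smoking (Bernoulli 25%) and
  family history of VTE (Bernoulli 15%). Family history is an
  independent risk factor here, not derived from relatives' genotypes —
  no pedigree model is attempted.
* **Effects**: the default `study_panel()` uses the nine published
  per-allele odds ratios (6.46 and 5.32 for the two thrombophilia
  variants down to 0.60 for the protective ABO marker) and the four
  clinical per-unit odds ratios (1.01 age, 1.07 BMI, 1.63 smoking,
  2.13 family history), plus null decoy SNPs (default 30, frequencies
  uniform on [0.05, 0.5]) standing in for the untyped remainder of a
  46-SNP candidate panel.
* **Prevalence**: the generating intercept is auto-calibrated by a
  mean-field approximation to a target population prevalence of 1%.
  VTE among CC users is on the order of a per-mille per year, so over a
  multi-year exposure window a percent-scale cumulative risk is the
  realistic regime; it matters because only in the rare-disease regime
  does the odds ratio approximate the risk ratio, giving case
  allele-frequency enrichment of the size actually reported for
  case-control panels (e.g. a frequency-0.02, OR-6.5 variant rises to
  roughly 0.10 in cases). A common-disease setting visibly attenuates
  that enrichment.
* **Structured missingness**: `study_missingness()` reproduces the
  ascertainment-bias correction of the emulated design — family history
  and the two thrombophilia genotypes set to missing in a 523-control
  subset recruited through thrombophilia screening. The generator
  reproduces the *masking*, not the recruitment bias the masking
  neutralised: the masked controls are drawn from the same population
  as everyone else.

Because the generator draws independent SNPs with clean additive
effects, passing tests demonstrate that the machinery recovers what it
assumes — they do not certify performance under linkage disequilibrium,
genotyping error, effect heterogeneity, or confounded recruitment.

## Numerical and design choices

* **IRLS convergence**: absolute log-likelihood change below $10^{-8}$,
  at most 100 iterations. Coefficients and standard errors agree with
  `stats::glm` to $10^{-6}$ on the suite's cross-checks; the iteration
  itself is compiled (RcppArmadillo) because ensemble runs perform
  hundreds of thousands of fits.
* **Separation**: a fit whose coefficients exceed 15 in absolute value
  (odds ratio above $3\times10^6$) or whose information matrix is not
  invertible is reported as non-converged; stepwise moves into such
  fits are skipped rather than accepted with exploded coefficients.
  Rare alleles (frequency around 0.01) in half cohorts make this a
  live concern.
* **Strict AIC descent**: a move is accepted only if it lowers the AIC
  by more than $10^{-8}$, so the accepted path is strictly decreasing
  and floating-point ties cannot cycle. Equal-AIC moves resolve
  deterministically in lexicographic variable-name order, additions
  scanned before deletions.
* **Stepwise direction**: bidirectional from the intercept-only model
  by default — the emulated description ("stepwise, while the AIC
  improves") does not fix a direction; forward-only and backward-from-
  full are available for sensitivity analysis, as is a `force` list
  for variables that must stay in every model (the default lets
  clinical variables compete freely).
* **Imputation donors**: by default each replicate imputes the full
  cohort from all observed control values *before* splitting — the most
  literal reading of the emulated procedure. This leaks a little
  information between train and test halves through imputed cells; the
  strict `donor_mode = "train_controls"` splits first and restricts
  donors to training-half controls. Draws are with replacement
  (without-replacement is ill-defined once the missing count exceeds
  the pool).
* **Seed schedule**: replicate $i$ runs under
  `bitwXor(master_seed, i)`. Replicates are therefore reproducible
  individually, independent of execution order, prefix-consistent when
  the replicate count changes, and shared across every model evaluated
  in a comparison.
* **Wilcoxon descriptives**: exact enumeration for tie-free groups of
  at most 25, otherwise the normal approximation with tie and
  continuity correction.
* **Fisher QC filter**: two-sided by summation of hypergeometric table
  probabilities no larger than the observed table's; a variant is kept
  only when $p$ is strictly above the threshold (default 0.01), and
  variants without reference counts pass with a warning.
* **ROC renderings**: whether a multi-replicate ROC figure should pool
  all test-half scores or vertically average per-replicate curves is
  genuinely ambiguous; `compare_models()` can produce both, labelled
  `pooled` and `averaged`.

## Scale of the shipped checks

The test-suite and acceptance runs use study-scale cohorts (794 cases /
828 controls) with 1000 replicates for the selection-stability check
(10 decoy SNPs) and 500 replicates for parameter recovery and model
ordering, and smaller cohorts for unit-level properties. These sizes
are the package's choice of a desk-scale experiment that keeps
Monte-Carlo error well inside the asserted tolerances; the pipeline
defaults remain at 10,000 replicates.

## Known limitations

* No linkage disequilibrium, proxy-SNP handling, or pedigree modelling
  in the generator; no PLINK-format input.
* No interaction-term search — selected models are main-effects only.
  `interaction_screen()` offers a post-hoc pairwise Wald check of the
  final model's product terms, but interactions never enter selection.
* No penalised-regression alternatives to stepwise selection.
* No calibration assessment or clinical decision thresholds: the
  evaluation surface is discrimination (AUC) only.
* Published fixed-coefficient comparison scores must be supplied by the
  user as `refit = FALSE` model JSON; their literature coefficients are
  not bundled.
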