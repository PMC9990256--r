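---
title: "Log-ratio signatures: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-ratio signatures: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Sequencing-based abundance tables are compositional: a sample's counts are
constrained by its sequencing depth, so only ratios between taxa carry
information. Any method whose output changes when a sample is multiplied
by a positive constant is answering a question about the instrument, not
the community. `codasig` identifies a *predictive microbial signature* — a
small set of taxa whose balance discriminates a phenotype — while staying
inside the log-ratio framework of compositional data analysis throughout.

# Cross-sectional model

For `K` taxa we fit the generalized linear model containing **all**
`K(K-1)/2` pairwise log-ratios,

$$g(E(Y)) = \beta_0 + \sum_{1 \le j < k \le K} \beta_{jk}
\log(X_j / X_k),$$

with an elastic-net penalty on the `\beta_{jk}`. The penalty does the
variable selection; the all-pairs parameterization guarantees that
whatever is selected remains a function of ratios only. The selected
pairwise coefficients are then collapsed to per-taxon coefficients

$$\theta_j = \sum_{k > j} \beta_{jk} - \sum_{k < j} \beta_{kj},
\qquad \sum_j \theta_j = 0,$$

so the linear predictor is the log-contrast
$M = \sum_j \theta_j \log X_j$. The zero sum is structural (every
`\beta_{jk}` contributes `+\beta` to one taxon and `-\beta` to another),
which yields two useful invariants that the test suite checks to floating
precision: scores are unchanged under per-sample rescaling, and the
collapsed form reproduces the pairwise form exactly. Taxa with positive
`\theta` form group G1, negative `\theta` group G2; the signature reads as
a weighted balance of G1 over G2.

## Fitting and tuning parameters

* **`alpha` (default 0.9).** The elastic-net mix. Near-lasso sparsity is
  the point of the method; the small ridge component stabilizes selection
  among the strongly correlated log-ratio columns (all pairs sharing a
  taxon are correlated by construction).
* **Lambda grid.** 100 log-spaced values from `lambda_max` (the smallest
  penalty with an all-zero solution, as computed by glmnet) down by a
  factor of 1e-3 when samples exceed predictors, 1e-2 otherwise.
* **Cross-validation.** The path is refit on each of `nfolds` training
  folds (default 10; 5 inside the benchmark harness) and scored on the
  held-out fold: AUC for binary outcomes, mean squared error for
  continuous ones. Folds are class-stratified and derived from a caller
  supplied seed, so every fit is reproducible. The package's own midrank
  AUC is used for fold scoring, keeping tie handling identical everywhere.
* **`lambda_rule` (default `lambda.1se`).** The largest penalty whose CV
  performance is within one standard error (sd across folds / sqrt(folds))
  of the best. This is deliberately conservative: it trades a little
  accuracy for considerably fewer selected taxa. `lambda.min` is
  available when raw accuracy matters more than parsimony.
* **Pseudocount (default 1).** Zeros are replaced by adding the
  pseudocount to *every* entry of the table before the log transform,
  keeping the benchmark protocol exact and the transformation monotone
  per column. More elaborate model-based zero replacement is intentionally
  out of scope.
* **Covariates.** Non-compositional covariates are fit first by an
  unpenalized GLM; their fitted linear predictors enter the penalized fit
  as a fixed offset, so the signature only captures microbial structure
  beyond the covariates. Rank-deficient covariate matrices are rejected by
  name rather than silently dropped.
* **Binary coding.** Factor outcomes keep their level order (second level
  is the "case"); unordered labels are sorted lexicographically with the
  second label coded 1; `case_level` overrides either.
* **Standardization.** Log-ratio columns are standardized inside the
  solver (glmnet's default) and coefficients are reported back on the
  log-ratio scale. With columns that share a common log scale this mainly
  equalizes the influence of high- and low-variance ratios.

Reported accuracy is two numbers: the *apparent* metric (signature applied
to its own training data; optimistic) and the cross-validated metric at
the chosen lambda, with its between-fold standard error. Note that the CV
value at the selected lambda is still the value that won the selection, so
under a true null it sits slightly above 0.5 on average; the null
calibration test bounds this bias.

# Longitudinal model

With repeated observations per subject, the trajectory of a log-ratio is
summarized by its integral over a window `[l1, l2]`, linearly
interpolating between observations. Positive summaries mean the numerator
taxon ran above the denominator taxon across the window. Because
integration is linear, only the `K` per-taxon integrals
$I_{ij} = \int_{l_1}^{l_2} \log X_{ij}(t)\,dt$ are computed; every
pairwise summary is the exact floating-point difference `I_j - I_k`. The
penalized fit and the collapse are then identical to the cross-sectional
case with summaries in place of log-ratios, and the per-subject score
$M_i = \sum_j \theta_j I_{ij}$ equals the integral of the subject's
log-contrast trajectory — an identity the tests verify numerically.

Design choices that the data forced:

* **Filtering before imputation.** Subjects with fewer than 2 in-window
  observations carry no trajectory and are dropped; a taxon is kept only
  when at least `ceiling(0.7 × subjects)` subjects show it in ≥ 3 nonzero
  observations. The nonzero rule is only meaningful on the raw table, so
  the pipeline filters first and imputes afterwards.
* **Partial window coverage.** When a subject's observations do not span
  the full window, the integral over the covered sub-interval is rescaled
  by `(l2 - l1) / covered length`. No extrapolation is performed: the
  rescaling keeps summaries comparable across subjects without inventing
  observations. The alternative (integrating only the covered part)
  would conflate trajectory level with observation span.
* **No smoothing, no alignment.** Observation times may differ freely
  across subjects; linear interpolation is the only trajectory model.
  Human cohort data rarely supports more (few, irregular time points);
  spline or mixed-effects trajectory models are explicitly out of scope.
* **Duplicate `(subject, time)` records are an error**, not averaged —
  the ambiguity should be resolved upstream.
* **The window is a required argument.** It is a scientific choice (e.g.
  the first three months of life), not something the package can default.

# The simulation benchmark

`synthetic_template()` + `simulate_case_control()` reproduce a standard
template-based spike-in design: keep the most prevalent template taxa,
pick true-positive taxa uniformly, multiply their proportions by the
effect size in the case group, re-close, and draw every sample
multinomially at fixed depth. Post-processing removes taxa below 5%
prevalence (strictly below; exactly 5% is kept) and adds a pseudocount
of 1. Raw per-sample totals equal the depth exactly, groups are
exchangeable at effect size 1, and the case/control enrichment of the
spiked set has the closed form `e / (1 + (e - 1) p_{TP})` against which
the simulator is verified by Monte Carlo.

The synthetic template draws proportions from a log-normal with
`lognormal_sigma = 4`. This produces the strong dominance structure of
real faecal communities — the top taxon holds roughly half the community
and a 2000-read sample observes on the order of 75 taxa, leaving a few
hundred taxa after the 5% prevalence filter. Flatter templates (sigma
near 2) are unrealistic for stool: most of 2000 taxa would survive a 5%
prevalence filter at 2000 reads, which real faecal data does not show.

What the generators deliberately do **not** emulate: phylogenetic
correlation between taxa, overdispersion beyond multinomial sampling,
batch effects, and longitudinal dynamics of real infant cohorts (the toy
trajectory generator plants a single elevated taxon against a stable
reference). Passing tests therefore demonstrate correctness of the
machinery and qualitative behaviour — recovery, calibration, the
effect-size trend — not performance on any particular real dataset.

# Evaluation harness

`stratified_kfold()` deals shuffled class members round-robin, so per-fold
class counts differ by at most one and identical seeds give identical
folds; all methods inside a benchmark replicate share one assignment.
`auc_score()` is the midrank Mann–Whitney statistic (ties count one half)
and is tested against exhaustive pair counting for every labelling of up
to eight samples, and against an independent implementation. The
differential-abundance baseline mirrors common practice: per-taxon
two-sample rank test on relative abundances, Benjamini–Hochberg selection
at 0.05, then a logistic model on the selected taxa (with a 1e-8 ridge so
complete separation stays finite); zero selections score a constant. Any
external DA method can be plugged in through `per_taxon_test`.

# Numerical notes

* `theta` entries below 1e-12 in magnitude are zeroed after the collapse;
  selection itself produces exact zeros, the guard only absorbs solver
  noise.
* The nonzero count along the penalization path is non-increasing in the
  penalty up to single-variable transient exits — coordinate-descent
  paths let a variable leave the active set occasionally, so the property
  tests allow dips of one.
* Ties in the CV curve are resolved towards the larger penalty (the
  sparser model).
* Perfect separation in penalized logistic fits is left to the penalty;
  only an unpenalized fit could diverge.

# Problem sizes used in the checks

The property suite fits 50 small signatures (60 samples, 6 taxa), runs 20
permuted-label fits per study type (100 samples / 15 taxa
cross-sectional; 30 subjects / 8 taxa longitudinal), 10 recovery fits per
study type, and a scaled benchmark of 3 replicates × 3 effect sizes
(1.25, 2, 5) at 50 samples per group on a 2000-taxon template at depth
2000 with 5-fold evaluation. These sizes were chosen so the full suite
completes in minutes on a laptop while each check retains clear
statistical resolution (e.g. ±0.03 on a null AUC averaged over 20 seeds).

# Known limitations

* No inference on `theta` — no p-values or confidence intervals; the
  method targets prediction and the cross-validated metric is the honest
  summary of its quality.
* Selection is not sub-composition invariant: removing taxa from the
  input can change which balance is found (scores of a *fixed* signature
  are invariant; the search is not).
* The pseudocount is a pragmatic zero treatment; signatures involving
  low-prevalence taxa can be sensitive to it.
* Multi-class outcomes, time-varying outcomes and mixed-effects
  trajectory models are out of scope.
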