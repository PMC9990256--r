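# codasig

Sparse, predictive microbial signatures from compositional microbiome data.

Microbiome abundance tables are compositional: only the relative sizes of
the taxa carry information, and analyses that ignore this produce spurious
associations. `codasig` works entirely on log-ratios. To relate a phenotype
*Y* to a composition *X* = (*X*₁, …, *X*ₖ) it fits the **all-pairs
log-ratio model**

> g(E(Y)) = β₀ + Σ₁≤j<k≤K β
> <sub>jk</sub> · log(X<sub>j</sub>/X<sub>k</sub>)

by cross-validated elastic-net regression (mixing parameter α, default 0.9;
penalty strength λ chosen by the one-standard-error rule). The selected
pairwise coefficients collapse to per-taxon coefficients

> θ<sub>j</sub> = Σ<sub>k>j</sub> β<sub>jk</sub> − Σ<sub>k<j</sub> β<sub>kj</sub>,  with Σ<sub>j</sub> θ<sub>j</sub> = 0,

so the signature score M = Σ θ<sub>j</sub> log X<sub>j</sub> is a
**zero-sum log-contrast**: a weighted balance between a positively
contributing taxon group (G1) and a negatively contributing group (G2),
invariant to rescaling any sample. For **longitudinal studies** the same
selection runs on per-subject integrals of the pairwise log-ratio
trajectories over a time window (linear interpolation between
observations); by linearity only K per-taxon integrals are ever computed,
and the fitted score equals the integral of the subject's log-contrast
trajectory.

The package also ships the pieces needed to benchmark such methods: a
template-based case–control read-count simulator (multinomial sampling
from a spiked template), a seeded stratified k-fold harness with a
midrank-AUC metric, and a differential-abundance baseline (per-taxon rank
test, Benjamini–Hochberg selection, logistic classifier).

Intended users: microbiome researchers who want interpretable taxon
balances with honest cross-validated accuracy, and method developers who
need a reproducible simulation benchmark.

## Worked example

Simulate a benchmark dataset (synthetic faecal-like template, 2000 taxa,
2000 reads/sample, 50 samples per group, effect size 2 on 100 spiked taxa,
5% prevalence filter + pseudocount), then fit a signature:

```r
library(codasig)

tpl <- synthetic_template(n_taxa = 2000, seed = 10)
sc  <- simulation_scenario(n_per_group = 50, effect_size = 2, seed = 10)
ds  <- benchmark_postprocess(simulate_case_control(tpl, sc))

res <- coda_signature(ds$table, ds$labels, pseudocount = 0,
                      nfolds = 5, seed = 10)
res
#> <coda_signature> binomial outcome, 3 taxa selected (2 pairs), rule lambda.1se
#>   G1 (+): tax0666
#>   G2 (-): tax0563, tax1410
#>   apparent AUC = 1.000
#>   cv AUC = 1.000 (se 0.0000) at lambda = 0.4937
```

Three taxa suffice: samples scoring high are enriched in `tax0666`
relative to `tax0563`/`tax1410`. The apparent AUC (signature applied to
its own training data) and the cross-validated AUC at the chosen λ are
both 1.0 here — at this effect size the groups are cleanly separable; at
effect size 1.25 the same pipeline reports a cv AUC around 0.77.
Diagnostics and exports:

```r
plot_cv_curve(res$fit)        # CV accuracy along the lambda path
plot_signature(res)           # signed bar chart of the selected balance
plot_prediction(res)          # score distributions per group
write_signature(res, "signature.tsv")
```

For a longitudinal study, supply a `longitudinal_table` (columns
`sample_id`, `subject_id`, `time` via `read_longitudinal_table()`), a
per-subject outcome and an integration window:

```r
fit <- coda_signature_longitudinal(lt, y, window = c(0, 90), seed = 1)
plot_signature_curves(signature_trajectory(fit))
```

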