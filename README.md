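# repokin

Quantitative analysis of depletion–repopulation experiments on CNS
macrophages. When microglia (MG) and CNS-associated macrophages (CAMs) are
transiently depleted with a brain-penetrant CSF-1R inhibitor and then allowed
to repopulate, the question is *how fast* each population and brain region
refills, and *from where* the new cells come. `repokin` packages the
statistics of that experimental design for immunologists and neurobiologists
running such studies:

- **Percent-of-control recovery.** Treated-group mean density as a
  percentage of the control mean, with the standard error propagated by the
  first-order delta method for a ratio of independent means:

  `SE% = 100 · sqrt( s²_T/(n_T·m²_C) + m²_T·s²_C/(n_C·m⁴_C) )`

- **Logistic repopulation kinetics.** The three-parameter logistic growth
  model `recovery(day) = L / (1 + exp(−k·(day − t₀)))` is fitted to per-day
  mean recovery by constrained multi-start nonlinear least squares, and the
  day the curve reaches 90% of control is derived analytically:

  `t₉₀ = t₀ − (1/k)·ln(L/90 − 1)`

- **Per-timepoint testing.** Welch two-sample t-tests (treated vs control)
  per day with Satterthwaite degrees of freedom and Bonferroni correction.
- **Fate mapping.** Pooled reporter-labeled fractions with Wilson and
  mouse-level bootstrap intervals, and an efficiency-normalized estimator of
  the HSC-derived fraction of a repopulated compartment from complementary
  (resident-lineage vs hematopoietic-lineage) reporter lines.
- **Cluster compositions.** Differential-abundance testing of replicate ×
  cluster tables via the arcsine square-root transform with t-test/ANOVA and
  Benjamini–Hochberg correction, plus chi-squared goodness-of-fit and
  independence tests and the Brunner–Munzel rank test for discrete scores.
- **Bulk RNA-seq gene prefilters.** Two low-expression rules and a
  pathway/biotype/substring blacklist with a full removal audit.
- **Synthetic cohorts.** A seeded generator reproducing the statistical
  structure of the design (logistic recovery + lognormal noise, binomial
  reporter labeling, Dirichlet-multinomial compositions), so every analysis
  stage is testable without any data download.

## Worked example

```r
library(repokin)

cfg       <- default_cohort_config(seed = 7)   # Fig-style 3 region x 3 cell type design
densities <- simulate_density_cohort(cfg)

crv <- recovery_curve(densities, "cortex", "MG")
round(crv[, c("day", "recovery_pct", "se_pct")], 2)
#>   day recovery_pct se_pct
#> 1   1         5.16   0.53
#> 2   5        67.64   3.92
#> 3  14       101.36   7.61
#> 4  56       108.62   5.29
#> 5  84        91.75   7.62
#> 6 182        95.95   4.90

fit <- fit_logistic(crv$day, crv$recovery_pct)
summary(fit)
#> Logistic repopulation fit: recovery = L / (1 + exp(-k (day - t0)))
#>   L  = 99.42 % of control
#>   k  = 0.9155 per day
#>   t0 = 4.175 days
#>   R-squared = 0.9785 on 6 points
#>   t90 (day the curve reaches 90% of control) = 6.64 days
```

Cortical microglia in this simulated cohort recover to ~99% of control with
an inflection at day 4.2 and cross 90% of control on day 6.6 — fast, as the
generating parameters (k = 1/day, t₀ = 4 d) dictate. The full per-stratum
report shows the spatial hierarchy the model encodes (microglia fastest,
perivascular macrophages slowest):

```r
report <- fit_kinetics_report(densities)
report$summary[report$summary$region == "cortex",
               c("cell_type", "L", "k", "t0", "r_squared", "t90_days")]
#>   cell_type     L      k     t0 r_squared t90_days
#> 4       lmM 94.68 0.4022  7.137    0.9869    14.49
#> 5        MG 99.42 0.9155  4.175    0.9785     6.64
#> 6       pvM 96.05 0.1714 10.930    0.9811    26.68
```

`welch_bonferroni_scan()` adds the per-day tests, `write_report()` /
`read_density_table()` handle TSV/JSON I/O, and
`inst/cli/repokin.R` exposes `simulate-cohort`, `kinetics`, `fatemap`,
`composition` and `prefilter` subcommands for shell pipelines.

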