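---
title: "Models and methods for CNS-macrophage repopulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for CNS-macrophage repopulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repokin)
```

## The experimental design this package models

Transient administration of a brain-penetrant CSF-1R inhibitor depletes
microglia (MG) and CNS-associated macrophages (CAMs); after withdrawal the
niches repopulate at population- and region-specific speeds, and the
subdural CAM compartment is partially replaced by hematopoietic-stem-cell
(HSC)-derived cells rather than by self-renewal. The measurements such a
study produces are (i) per-animal cell densities across brain regions and
days after treatment, in a treated and a control arm with unbalanced group
sizes; (ii) reporter-labeled cell counts from complementary fate-mapping
lines; (iii) replicate-by-cluster composition tables from single-cell data;
and (iv) bulk RNA-seq count matrices. `repokin` implements the estimators
and tests for all four, plus a generator that simulates cohorts with exactly
this structure.

## Percent-of-control recovery

For a (region, cell type, day) stratum with treated densities
$x_1,\dots,x_{n_T}$ and control densities $y_1,\dots,y_{n_C}$, recovery is
$R = 100\, \bar x / \bar y$ (% of control). Treating the two group means as
independent, the first-order delta method gives

$$\mathrm{SE}(R) = 100 \sqrt{ \frac{s_T^2}{n_T\,\bar y^2}
  + \frac{\bar x^2 s_C^2}{n_C\,\bar y^4} },$$

with $s^2$ the sample variances. Independence is justified because
different animals contribute to the two arms. Single-animal groups report an
`NA` standard error rather than a misleading zero.

First-order propagation of a ratio is accurate only while the control mean's
own coefficient of variation is small; as it grows, the true sampling
distribution of the ratio becomes skewed and wider than the linearization
predicts. The package's Monte-Carlo agreement check therefore uses groups of
ten animals, where animal-level CVs up to 0.3 keep the control-mean CV below
0.1; with only three or four control animals at high CV the delta SE should
be read as approximate.

Controls are **pooled** across sampling days by default, matching designs
with a single control group; `control = "per_day"` compares each day to its
own control animals and is the natural choice for simulated cohorts, which
sample controls at every timepoint.

## Logistic repopulation kinetics and $t_{90}$

Per-day mean recovery is fitted with the three-parameter logistic growth
curve

$$\mathrm{recovery}(d) = \frac{L}{1 + e^{-k (d - t_0)}},$$

where $L$ is the asymptote (% of control), $k$ the growth rate (per day) and
$t_0$ the inflection day. Fitting is nonlinear least squares on the per-day
means (not per-animal values; a `weights` argument accepts $1/\mathrm{SE}^2$
weighting but is off by default). The optimizer is Levenberg–Marquardt
(`minpack.lm::nlsLM`) under box constraints $L \in (0, 200]$,
$k \in (10^{-4}, 10]$, $t_0 \in [0, \max d + 30]$ — the caps prevent runaway
asymptotes on sparse designs. Initialization: $L_0$ is the observed plateau
clipped to $[50, 150]$; $t_{0,\mathrm{init}}$ the linearly interpolated
half-max crossing; $k_\mathrm{init} = 4/(t_{75} - t_{25})$ with a fallback
of 0.5/day; five starts (the base values, $k/4$, $4k$, $0.5\,t_0$,
$1.5\,t_0$) guard against local minima, and the best converged start by
residual sum of squares wins. Degenerate inputs (flat recovery, fewer than
three points) return a flagged non-converged object, never an exception, so
batch reports keep failed strata visible.

The time to 90% of control solves the fitted curve for an **absolute**
threshold of 90% of the control mean (not 90% of $L$):

$$t_{90} = t_0 - \frac{1}{k} \ln\!\left( \frac{L}{90} - 1 \right),$$

defined only when $L > 90$ and $k > 0$; otherwise the result carries
`defined = FALSE` with a reason. Tests verify the analytic form against
bisection root-finding to $10^{-9}$ days. Days are the canonical time unit;
week-labeled inputs (`"8w"`) are converted at 7 days/week on read.

Per-day Welch t-tests with Satterthwaite degrees of freedom and Bonferroni
correction (default $m$ = number of tested days, six in the reference
design) accompany the fit. Two caveats are deliberate: with zero variance in
both groups the p-value is 1 (equal means) or 0 (unequal) by logged
convention; and deep-tail Welch p-values from very unbalanced tiny samples
(e.g. three treated animals against a large pooled control group) are
approximate, which is why the package's family-wise-error simulation uses
per-day controls.

## Fate-mapping ontogeny inference

Each reporter line labels one lineage with efficiency $e$: in a compartment
whose HSC-derived fraction is $f$, the expected labeled fraction is $e f$
for an hsc-class line and $e (1 - f)$ for a resident-class line. The
labeled fraction is estimated by pooling counts across mice (Wilson score
interval on the pooled counts, plus a mouse-level bootstrap since mice are
the biological replicates). The ontogeny estimator normalizes by a
reference fraction that measures $e$ directly — Ly6C-high blood monocytes
of the same animals for hsc-class lines, the same compartment in untreated
controls for resident-class lines — giving
$\hat f = \hat p_\mathrm{target}/\hat p_\mathrm{ref}$ (hsc) or
$1 - \hat p_\mathrm{target}/\hat p_\mathrm{ref}$ (resident), clipped to
$[0,1]$ with the clipping flagged. Confidence intervals resample mice in
both groups (2000 draws, seeded). A zero reference fraction leaves the
estimate undefined with a reason, since the efficiency cannot be
calibrated.

## Composition statistics

Replicate cluster proportions $p$ are transformed with the
variance-stabilizing $y = \arcsin \sqrt p$ and compared per cluster with an
unmoderated two-sided t-test (two conditions; pooled variance by default, a
Welch option exists) or one-way ANOVA (three or more), followed by
Benjamini–Hochberg adjustment across clusters. The published workflow this
mirrors also offers empirical-Bayes moderation of the variances; that
refinement is intentionally out of scope here, and with the small replicate
numbers typical of these designs the unmoderated test is slightly
conservative. Chi-squared tests (goodness of fit against expected counts,
independence from margins; no Yates correction by default, flag available)
cover discrete count graphs. The Brunner–Munzel test estimates the relative
effect $\hat p = P(A < B) + \tfrac12 P(A = B)$ via mid-ranks and
studentizes it with Welch-type degrees of freedom; completely separated or
constant samples have zero rank variance, and the implementation then
raises a structured error suggesting an exact/permutation approach rather
than returning an infinite statistic (identical constant samples return
$\hat p = 0.5$, $p = 1$).

## Gene prefilters

Bulk RNA-seq matrices are cleaned in a fixed order: user-supplied pathway
gene sets, then biotype blacklist (requires a gene-to-biotype map), then the
substring blacklist, then a low-expression rule. The default substring list
(`Mrp`, `Rpl`, `Rps`, `Sn`, `Sf`, `Gtf`, `Med`, `Rbm`, `Rik`, `Atp`,
`Nduf`, `Tomm`, `Pol`, `Anap`, `Rna`, `Dna`, `Gm`, `Ddx`, `Smim`, `Bola`,
`Timm`, `Micos`) is matched case-sensitively **anywhere** in the symbol:
`Rik` is a suffix in murine placeholder symbols, so prefix-only matching
would miss it. Short tokens such as `Sn` are aggressive by construction
(e.g. `Snca` is removed); the list is applied verbatim, fidelity over
biological caution. Two low-expression rules: the *fraction rule* removes a
gene whose per-sample count is below 10 in at least 75% of samples (the
alternative row-sum reading is available behind `row_sum = TRUE`); the
*total rule* removes a gene whose total count is strictly below half the
number of samples. Every removal is logged once with stage and reason;
each filter partitions its input and is idempotent.

## The synthetic-cohort generator

The generator exists so that every pipeline stage can be exercised, with
known ground truth, at the scale of the real design. Its defaults mirror
that design: sampling days 1, 5, 14, 56, 84 and 182 (weeks converted at
×7), treated group sizes 3/5/6/4/4/4, control groups of three, three
regions by three cell types with fast microglial (k = 1/day, t₀ = 4 d),
intermediate leptomeningeal and slow perivascular (k = 0.15/day,
t₀ = 12 d) kinetics toward an asymptote of 98% of control, and a noise CV
of 0.15 — a typical between-animal spread for flow-cytometry or histology
densities.

Choices worth knowing:

- **Noise model.** Density variability is multiplicative lognormal with
  $\sigma^2 = \ln(1 + \mathrm{CV}^2)$, mean-corrected so the expected
  density equals the curve. No distributional form is implied by the assay
  itself; lognormal was chosen because densities are positive and
  heteroscedastic. This is a stand-in, and tests passing under it say
  nothing about heavier-tailed real data.
- **Controls at every timepoint** (simulation clarity); analyses may still
  pool them.
- **Seed fan-out.** One global integer seed derives per-stream child seeds
  from (seed, stream-key) so adding a region or line never perturbs other
  strata's draws; identical configs give byte-identical tables.
- **Phenomenological, not mechanistic.** Cohorts are draws around a logistic
  mean curve; there is no birth–death or niche competition model, so the
  generator cannot probe model misspecification, only estimator behavior
  under the assumed model.
- Reporter labeling is binomial per mouse (no overdispersion between mice
  beyond sampling); compositions are Dirichlet-multinomial with a single
  concentration parameter.

## Verification scale

The packaged checks run at deliberately chosen sizes: 200 simulated cohorts
per kinetic regime for $t_{90}$ recovery, 1000 null cohorts for the
family-wise error of the Welch–Bonferroni scan, 1000 Dirichlet-multinomial
datasets for the composition test's type-I error, 500 binomial cohorts for
ontogeny recovery, $10^5$ Monte-Carlo draws per grid cell for the
standard-error comparison, and 1000 random curves for the analytic-vs-numeric
$t_{90}$ agreement — large enough that the simulation error is small against
each tolerance, small enough to run routinely. `scripts/acceptance.R`
recomputes all of them from a single `--seed`.

## Known limitations

- The logistic fit uses per-day mean recovery; per-animal fitting (nonlinear
  mixed models) would propagate animal-level uncertainty into the parameters
  but is outside the present scope.
- Delta-method standard errors and deep-tail Welch p-values are
  approximations whose quality degrades in the smallest groups, as discussed
  above.
- The composition test is unmoderated; with very few replicates an
  empirical-Bayes variant would gain power.
- The ontogeny estimator assumes the reference fraction measures the same
  labeling efficiency that applies in the target compartment, and that
  lineage classes are mutually exclusive and exhaustive.
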