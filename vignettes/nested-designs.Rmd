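---
title: "Cluster-related variation in nested two-condition experiments: models, simulation design, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-related variation in nested two-condition experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many experiments in the life sciences collect several measurements inside the
same sampling unit — boutons within a neuron, cells within an animal, pups
within a litter, wells within a culture plate. Observations sharing a cluster
are more alike than observations from different clusters, and any analysis
that treats them as independent misprices its own uncertainty. `nestpower`
studies the two-condition, two-level version of this problem for two layouts:

* **Design A** — condition is a *cluster-level* variable `Z_j`: every
  observation in a cluster has the same condition (e.g. genotype).
* **Design B** — condition is an *observation-level* variable `X_ij`: both
  conditions occur inside every cluster (e.g. treated and untreated cells
  from the same animal).

Design B is the interesting case, because *two* things can vary over
clusters: the mean of the control condition (the intercept) and the effect of
the manipulation itself (the slope).

## The model

For design B the package simulates and fits the linear mixed model

$$Y_{ij} = \beta_{0j} + \beta_{1j} X_{ij} + e_{ij}, \qquad
  e_{ij} \sim N(0, \sigma^2_e),$$

$$\beta_{0j} = \gamma_{00} + u_{0j}, \qquad
  \beta_{1j} = \gamma_{10} + u_{1j}, \qquad
  (u_{0j}, u_{1j}) \sim N\!\left(0,
  \begin{pmatrix} \sigma^2_{u0} & \sigma^2_{u0,u1} \\
                  \sigma^2_{u0,u1} & \sigma^2_{u1} \end{pmatrix}\right).$$

Condition is dummy coded 0/1 throughout (no ±0.5 contrast coding anywhere in
the generator), so $\sigma^2_{u0}$ is the between-cluster variance of the
*control-condition* mean and $\sigma^2_{u1}$ is the variance of the
experimental effect over clusters. Design A drops the slope terms and moves
the condition indicator to the cluster level.

Two standardized summaries parameterise everything user-facing:

* the **effect size** $d = \gamma_{10} / \sigma_e$, and
* the **intracluster correlation**
  $ICC = \sigma^2_{u0} / (\sigma^2_{u0} + \sigma^2_e)$.

`resolve_params()` inverts these onto variance components under the package's
scale convention $\sigma^2_e = 1$ (so $\gamma_{10} = d$ and ICC values 0,
1/4, 1/3, 1/2 map to $\sigma^2_{u0}$ = 0, 1/3, 1/2, 1). Results are scale
invariant, which is why fixing the residual variance loses nothing. ICC = 1
("complete dependency") is excluded: it has no finite intercept variance
under a fixed residual variance.

## Parameters that matter, and their defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `d` | standardized overall effect | — | 0.2 / 0.5 / 0.8 are the conventional small/medium/large benchmarks |
| `icc` | relative intercept variance | — | 0–0.5 covers the range commonly reported for nested neuroscience data |
| `var_u1` | slope variance (0/1 coding) | 0 | 0.05 / 0.10 / 0.15 are the conventional small/medium/large benchmarks; 0.025 probes "very small" |
| `var_e` | residual variance | 1 | scale convention, see above |
| `cov_u0u1` | intercept–slope covariance | 0 | zero in all canonical simulation cells; supported by the generator and estimable by the full model |
| `alpha` | two-sided test level | 0.05 | convention |
| `n_reps` | Monte-Carlo replicates | 10,000 | gives binomial SE ≤ 0.5 points on any rate; scaled down where mixed-model fits dominate runtime |

`effect_dispersion_interval()` translates a slope variance into something a
scientist can argue about: with $d = 0.5$ and the "small" $\sigma^2_{u1} =
0.05$, cluster-specific effects have sd $\approx 0.22$ and 95% of them lie
roughly between 0.07 and 0.93 — i.e. even "small" slope variance spans
essentially absent to almost double the average effect.

## What the generator emulates — and what it does not

`generate_design_b()` draws cluster effects via the lower-triangular factor
of the 2×2 covariance (valid for singular matrices, so boundary settings like
`var_u0 = 0` are exact), then adds i.i.d. Gaussian residuals. It emulates:

* balanced designs — exactly `nc` observations per condition per cluster;
* Gaussian random effects and residuals, homoscedastic within cluster;
* a cluster-level covariate (`generate_with_cluster_covariate()`) that
  carries a chosen fraction of the slope variance, leaving the marginal
  slope variance unchanged.

It deliberately does **not** emulate: unbalanced cluster sizes (user-supplied
unbalanced data are accepted by the estimators, but the generator's contract
is balance — the summary-statistics comparisons assume it), non-normal or
heteroscedastic noise, more than two conditions, or a third nesting level.
A green Monte-Carlo test therefore establishes the behaviour of the
*estimators under the stated Gaussian, balanced world*, not robustness to
messier data.

Reproducibility: a master seed spawns one child seed per replicate
(`replicate r` depends only on the master seed and `r`), and every method is
fitted on the *same* replicate datasets (common random numbers), which
sharpens between-method power contrasts without biasing marginal rates.

## The competing analyses

* `ttest_individual()` — pooled-variance Student t on all observations,
  ignoring clusters. Pooled rather than Welch by design: group sizes are
  equal by construction and the conventional analysis this package studies
  predates routine Welch defaults (`welch = TRUE` is available).
* `paired_ttest_means()` — one-sample t on the `N` within-cluster
  condition-mean differences (df `N − 1`).
* `ttest_cluster_means()` — the design-A analogue on cluster means.
* `lmm_intercept()` — random-intercept multilevel model ("multilevel I");
  misspecified for design B whenever slope variance exists.
* `lmm_intercept_slope()` — random intercept + random slope ("multilevel
  II"), the correctly specified model.
* `fixed_effects_dummies()` — OLS with `N − 1` cluster indicators, computed
  by within-cluster centering (Frisch–Waugh; algebraically identical, no
  `N`-column model matrix).
* `lmm_covariate()` — multilevel II plus fixed `w` and `w:X` terms for a
  cluster-level covariate.

### Numerical and inferential choices

* **Mixed models are fitted by `lme4`** (REML by default, ML behind a flag).
  This is a deliberate buy-not-build decision: `lme4` is the de facto
  standard fitter for this model family in practice, so its estimates are
  the ones whose operating characteristics are actually at stake;
  re-deriving a profile-likelihood fitter would add risk without adding
  information.
* **Wald z p-values** for mixed models: `estimate/SE` against the standard
  normal, no denominator degrees of freedom — the fitter's own default
  convention, and the one practitioners who read its summary output
  effectively use; a Satterthwaite correction is intentionally out of scope.
  At very small `N` this is mildly anticonservative — the Monte-Carlo
  layer, not the z approximation, is the authority there.
* **Boundary variance estimates are reported as 0**, never negative;
  singular fits are *kept* (`converged = FALSE` only on optimiser failure),
  and the Monte-Carlo layer counts and excludes genuine failures from the
  denominator, warning when more than 2% of replicates drop.
* **Degenerate data** (zero residual variance) yield `se = 0`; the result is
  flagged by `statistic = ±Inf` and `p ∈ {0, 1}` by the sign of the
  estimate rather than NaN.
* **Ties/allocation**: design A assigns the first half of clusters to
  control, the second half to treatment — a package convention; with
  exchangeable clusters any fixed allocation is distributionally
  equivalent.

## Closed forms

With standardized data and a balanced design, the standard error of the
overall effect in multilevel analysis is

$$SE_{\gamma_{10}} = \sqrt{\frac{nc\,\sigma^2_{u1} + \sigma^2_e}{nc\,N}},$$

whereas the conventional individual-observation analysis assumes

$$SE_{\beta_1} = \sqrt{\frac{\sigma^2_e}{nc\,N}}.$$

Comparing the two explains both headline phenomena: the naive SE omits the
$nc\,\sigma^2_{u1}$ term, so its p-values are biased downward — increasingly
so as `nc` or $\sigma^2_{u1}$ grow — and the multilevel SE has a floor
$\sqrt{\sigma^2_{u1}/N}$ that more observations per cluster cannot breach,
so power plateaus in `nc` but not in `N`. The intercept variance appears in
neither expression, which is why the misspecified random-intercept model's
inflation is ICC-invariant.

Two conventions coexist here, on purpose. The display equations above hold
for *standardized* data; the sampling variance of the dummy-coded (0/1)
mean-difference estimator differs by constant factors
($\mathrm{var}(\hat\gamma_{10}) = \sigma^2_{u1}/N + 2\sigma^2_e/(nc\,N)$).
`se_gamma10()`/`se_beta1_naive()`/`analytic_power_design_b()` implement the
standardized forms exactly as conventionally printed; the quantitative
type-I prediction for the dummy-coded simulations is a separate derivation,
`analytic_type1_naive_ttest()`:

$$\text{type-I} = 2\left(1 - \Phi\!\left(z_{1-\alpha/2}\,
  \frac{se_{naive}}{sd_{true}}\right)\right),\quad
  sd_{true} = \sqrt{\tfrac{\sigma^2_{u1}}{N} + \tfrac{2\sigma^2_e}{nc\,N}},\quad
  se_{naive} = \sqrt{\tfrac{2(\sigma^2_e + \sigma^2_{u0} + \sigma^2_{u1}/2)}{nc\,N}}.$$

The intercept variance cancels from $sd_{true}$ (both conditions share each
cluster's intercept) but inflates the pooled within-group variance in
$se_{naive}$ — so, perhaps counterintuitively, more intercept variance makes
the naive t test *less* inflated (≈34% vs ≈50% at the large-slope-variance
cell), while leaving the misspecified multilevel model untouched. The
formula uses the expectation of the naive variance estimate, ignoring its
sampling noise; at the `nc·N` sizes of interest this approximation is well
inside Monte-Carlo error, and the test suite checks it against brute-force
simulation rather than asserting it axiomatically.

The analytic power curve uses the normal approximation (no t correction),
appropriate for its planning role; at small `N` trust the simulation.

## Monte-Carlo studies

`replicate_study()` reruns the four canonical studies: 1a/1b measure *power*
($d \in \{0.2, 0.5\}$, no slope variance, ICC absent/present, `N` 10 or 30,
`nc` 5–50); 2a/2b measure the *false positive rate* ($d = 0$,
$\sigma^2_{u1}$ 0.025–0.15, ICC absent/0.5, `N = 50`, `nc` 5–105). Default
`nc` grids step by 10 (curve shape, not grid density, is the reproduction
target); finer grids via `nc_grid`. The headline numbers, reproduced by the
acceptance suite at 10,000 replicates for t-test pipelines and scaled-down
replicate counts for mixed-model cells (stated per test):

* naive t test, study 2a: type-I error ≈ 20% at $\sigma^2_{u1} = 0.025$,
  ≈ 50% at 0.15 (nc = 105);
* study 2b (ICC = 0.5): ≈ 35% for the naive t test, ≈ 50% for the
  misspecified multilevel model;
* paired t test and multilevel II: nominal 5% throughout;
* study 1b (d = 0.2, ICC = 0.5, N = 10): the naive t test loses up to
  ≈ 25 percentage points of power relative to multilevel analysis.

## Known limitations

* Wald z inference for mixed models is mildly anticonservative at small `N`;
  no Satterthwaite/Kenward–Roger option.
* The analytic type-I formula is asymptotic in `nc·N`; below a few hundred
  total observations use the simulator.
* No Bayesian estimation for very few clusters, no 3-level nesting, no
  unbalanced generation, no cost-optimal allocation solver (the power grid
  is the planning tool; optimal allocation is delegated to specialised
  software).
* `generate_with_cluster_covariate()` sets the intercept–slope covariance of
  the *residual* slope component to zero when part of the variance is
  explained; a nonzero covariance is only supported unexplained.
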