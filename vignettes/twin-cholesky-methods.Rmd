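---
title: "Methods: bivariate Cholesky twin models for longitudinal BMI and height"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bivariate Cholesky twin models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(twinace)
```

## The statistical model

`twinace` analyzes one phenotype (log-BMI or height) measured at two ages
(j, k) in twin pairs. Per family the observed vector is
(twin1@j, twin1@k, twin2@j, twin2@k), modelled as multivariate normal.
Its covariance is built from three latent components with lower-triangular
2×2 path matrices:

- within-twin block: `Sigma = L_A L_A' + L_C L_C' + L_E L_E'`;
- cross-twin block: `k * L_A L_A' + L_C L_C'`, with the additive-genetic
  scaling `k = 1` for MZ pairs, `0.5` for same-sex DZ pairs and
  `0.5 * rg_os` for opposite-sex pairs, where `rg_os` in [0, 1] is
  estimated freely (sex limitation). The shared environment correlates 1
  across co-twins in every group — including OSDZ pairs, i.e. qualitative
  sex differences in C are not modelled — and the unique environment is
  uncorrelated across twins.

In the five-group design (`MZM, MZF, DZM, DZF, OSDZ`) male and female path
sets are estimated jointly; the OSDZ cross-twin block mixes the male
(twin 1) and female (twin 2) sets. Zygosity groups receive separate mean
parameters (DZ twins are slightly taller and heavier than MZ twins), while
total variances are equal across zygosity by construction — the standard
identifying assumption of the classical twin design.

Standardizing each component covariance gives the genetic, shared- and
unique-environmental correlations between ages, tied to the phenotypic
correlation by the identity

```
r(P1, P2) = a1*rA*a2 + c1*rC*c2 + e1*rE*e2
```

with `a, c, e` the square roots of the standardized variance components.
This identity is exact in the model and is verified to 1e-8 for every
converged grid cell in the test suite. The AE model (no C) is the main
model; ACE is kept as a sensitivity model — the nesting
`logL(ACE) >= logL(AE)` is asserted in tests. Negative cross-age shared-
environment covariances remain representable through the sign of the
off-diagonal `L_C` entry even though each age's `c²` stays non-negative.

## Estimation

The likelihood is full-information ML: each family contributes the normal
log-density of its observed sub-vector under the sub-setted expected mean
and covariance. Families are grouped by (zygosity, missingness pattern)
and summarized by sufficient statistics (n, Σx, Σxx'), so an evaluation
costs O(#patterns) small-matrix operations independent of sample size.
Families in which one co-twin is entirely unobserved at both ages are
dropped and counted: after residualization (means ≈ 0) they carry no
co-twin covariance information.

Optimization is quasi-Newton (BFGS) on an unconstrained parameterization:
path entries and means are free reals (column signs of each L fixed
afterwards so diagonals are non-negative — `L L'` is invariant, and the
sign convention makes the reported solution unique), `rg_os` mapped
through a logistic onto [0, 1]. Gradients are analytic score equations
(validated against central differences in the tests). Starting values are
Falconer/method-of-moments estimates computed from double-entry twin
correlations, floored at 0.05 per variance share; if the convergence
check fails (scaled gradient norm ≥ 1e-5 per family, or more than 1% of
families needing a covariance jitter), up to three deterministic restarts
from perturbed starts (factors 0.9, 1.1, 0.75 on the path entries) are
attempted and the best point is kept, flagged `converged = FALSE` if the
check still fails. A numerically singular observed submatrix gets a 1e-8
diagonal jitter and is counted. Fits are deterministic: data plus
configuration reproduce estimates to machine precision.

Confidence intervals: `profile_ci()` inverts the likelihood-ratio
statistic against `qchisq(0.95, 1)`, re-maximizing all nuisance
parameters with the target quantity pinned by reparameterization (for a
component correlation, the second Cholesky column is written as
`t * (r0, sqrt(1 - r0^2))`; for univariate shares, scale and remaining
split are re-parameterized). Bounds are found by outward bracketing and
monotone bisection (default tolerance 1e-3 on the quantity scale), with
an end that cannot be bracketed inside the natural bounds returned at the
bound and flagged one-sided. Profile is the reference method; `wald_ci()`
(observed information plus delta method) is the default inside full
grids, where profiling every quantity of 171 bivariate fits would be
needlessly expensive — the two agree closely on well-behaved fits, which
is itself a test. The 95% profile CI for `rA` attains 89–99% empirical
coverage over 200 simulation replicates in the acceptance suite.

## The age-by-age correlation grid

`run_grid()` fits one bivariate model per unordered age pair — not a
single 19-variate model, which would be unidentifiable under the massive
structural missingness of pooled cohorts — and reports, per sex:
`r_trait`, `r_A`, (`r_C`,) `r_E` with CIs, the standardized paths, pair
counts and a convergence flag. Cells with fewer than `min_pairs`
(default 30; the source analyses do not state a minimum, so this is a
documented package choice) jointly informative pairs, or with a missing
zygosity group, are reported as skipped rather than silently dropped, and
non-converged cells keep their estimates plus a flag rather than being
blanked. No multiple-testing adjustment is applied; CIs are per cell.
Square-matrix serialization follows the convention: upper triangle males,
lower triangle females, diagonal empty. With ages 1–19 and both sexes the
grid holds 171 age pairs × 2 sexes = 342 genetic correlations.

## Preprocessing

BMI is weight (kg) divided by squared height (m²), log-transformed with
the natural log (the base only rescales, never changes correlations);
sample skewness (adjusted Fisher–Pearson) is reported before and after,
and defined as 0 for zero-variance samples so degenerate strata propagate
no NaN. Height enters untransformed, being near-normal already. Both are
residualized by OLS on [1, exact age, birth year, cohort indicators]
within each 1-year-age × sex stratum; log-BMI (not raw BMI) is
residualized, matching the order transformation-then-adjustment. A
rank-deficient stratum design drops columns deterministically from the
right (cohort indicators first, then birth year, then exact age) with a
warning; a stratum smaller than its design falls back to centring.
Measurements are binned to `round(exact_age)` clipped to [1, 19]; when a
twin has several measures in a bin the one closest to the bin centre is
kept (ties: first record). The binning rule is a package choice — the
source analyses do not state one.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a pooled longitudinal twin
database: a 38% MZ / 33% SSDZ / 29% OSDZ zygosity mix, ages 1–19, and
per-age/sex BMI and height moments taken from a packaged calibration
table of published descriptive statistics
(`default_growth_reference()`). Latent standardized phenotypes are built
as A + C + E with configurable per-age variance shares and cross-age
correlation matrices `R_A, R_C, R_E` (sampled through the spectral square
root with eigenvalues clipped at 0, so numerically semi-definite inputs
are tolerated); the cross-twin structure matches the analysis model,
including `rg_os`. BMI is generated on the log scale and exponentiated —
so the log-normalization step of preprocessing is exactly right for it —
and weight is derived as BMI·(height/100)², giving raw-looking records.
DZ means are shifted by a configurable offset; additive cohort and
birth-year effects supply nuisance signal for the residualization stage
to remove.

Default generative settings, chosen once as field-plausible values:
BMI `a2 = 0.6, c2 = 0.2, e2 = 0.2`, height `a2 = 0.8, c2 = 0.1,
e2 = 0.1`; cross-age decay 0.95 per year for A (high genetic continuity),
0.9 for C, 0.3 for E (unique environment is mostly occasion-specific,
including measurement error); `rg_os = 1`; 20% missingness per (twin,
age); birth years uniform on 1980–2010; three cohorts with small additive
offsets. Missingness is completely at random per (twin, age) — the real
attrition structure of pooled cohorts is unknown, so this is a documented
simplification, not an inference. The generator also does not model
assortative mating, chorionicity, secular BMI trends, correlation between
height and BMI, or within-bin repeat measures; passing tests therefore
demonstrate correctness of the estimation machinery under the stated
generative model, not robustness to those real-data features.

## Problem sizes and numerical choices

The test and acceptance suites run at deliberately modest sizes chosen to
keep Monte-Carlo error well inside the asserted tolerances: the full-age
grid uses 1,500 pairs (sufficient for every cell to clear the 30-pair
minimum under 20% missingness), parameter-recovery fits use 5,000 pairs
per zygosity group (recovery within ±0.04 for ACE, ±0.03 for AE), the
moment-oracle comparison uses 20 datasets of 2,000 MZ + 2,000 DZ pairs
(agreement within 3 MC standard errors), and the CI-calibration study
uses 200 replicates of 250 pairs per group. Likelihood evaluations based
on sufficient statistics make fit cost essentially independent of sample
size, so these sizes trade only Monte-Carlo precision, not fidelity.

Other numerical details: BFGS relative tolerance 1e-12 with up to 600
iterations; numerical Hessians at 1e-5 steps for Wald intervals; grid
rows sorted by (group, family id) before aggregation so results are
invariant to input row order; component correlations outside [-1, 1] by
less than 1e-8 are clipped with a warning, larger excursions are errors.

## Known limitations

- Dominance (ADE) and gene–environment interaction models are out of
  scope, as are parametric growth-curve models: the pairwise bivariate
  design estimates correlations, not trajectories.
- Per-sex estimates from five-group fits carry roughly double the
  Monte-Carlo error of pooled fits at the same total n; recovery checks
  at tight tolerances use the pooled design.
- `rg_os` is mapped logistically onto [0, 1]; when the truth sits at the
  boundary the estimate approaches but never exactly reaches it.
- Whether published per-sex matrices derive from joint five-group fits or
  sex-separate fits is generally not stated; both are implemented here,
  with five-group the default and `single_sex` available for stratified
  reruns and recovery studies.
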