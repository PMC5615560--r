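---
title: "Methods: spatial variance partitioning for county obesity rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial variance partitioning for county obesity rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countycar)
```

## The model

`countycar` fits an ecological linear regression of county obesity
prevalence (a rate in percent, one observation per county) on geographic
categorisations and environmental indicators, while splitting the residual
variation into a spatially clustered and an unstructured part:

$$ y_i \sim N(X_i\beta + s_i,\ \sigma_u^2), $$

in hierarchically centred form: the spatial effect $s_i$ enters the mean
rather than being an additive residual term, which improves Gibbs mixing.
$X_i$ collects an intercept, dummy-coded geographic categories (nine-level
urban-rural class, nine census divisions, four-level majority
race/ethnicity, five poverty quintiles; reference levels are the most-metro
class, New England, White non-Hispanic, and quintile 1) and, in the
extended regression, seven environmental indicators each rescaled to
$[0,1]$ by $(x-\min x)/\mathrm{range}(x)$ so that coefficient magnitudes
are comparable.

The spatial effects follow the intrinsic conditional autoregressive (ICAR)
prior: given all other counties,

$$ s_i \mid s_{-i} \sim N\!\Big(\tfrac{1}{L_i}\sum_{j \sim i} s_j,\
\sigma_s^2 / L_i\Big), $$

where $j \sim i$ ranges over the $L_i$ counties adjacent to $i$. Jointly
this is the improper pairwise-difference density
$\exp\{-\frac{1}{2\sigma_s^2}\sum_{i\sim j}(s_i-s_j)^2\}$, identified by a
sum-to-zero constraint because the model carries a separate intercept.
First-order interactions between the four categorical factors (six pairs)
are modelled as exchangeable random effects: each observed factor-level
pair cell $c$ of block $k$ gets $\gamma_{kc} \sim N(0, \sigma_k^2)$ with a
block-specific variance.

Two derived statistics summarise a fit:

* the **spatial fraction** $\Lambda = \mathrm{var}(s) /
  [\mathrm{var}(s) + \sigma_u^2]$, the share of residual variation
  attributable to the spatially clustered component (1 = fully clustered);
* **percent variation explained**, $100\,[1 - (\mathrm{var}(s) +
  \sigma_u^2)/\mathrm{var}(y)]$.

Both are computed per retained draw — $\mathrm{var}(s)$ is the empirical
variance of the $s$ vector across counties at that draw — and then
summarised by posterior means and equal-tailed 95% intervals. Per-draw
propagation preserves posterior uncertainty; a plug-in alternative using
realised residuals $y - X\beta - s$ is available via
`pct_variation_explained(realised = TRUE)`.

## Estimation

The sampler is a from-scratch two-chain Gibbs sampler (C++ core). All full
conditionals are conjugate: a multivariate Gaussian for $\beta$, the
single-site Gaussian above combined with the likelihood term for each
$s_i$, Gaussian shrinkage for interaction cells, and Gamma updates for the
precisions. Defaults follow the analysis protocol this package
re-implements: two chains of 10,000 iterations with the first half
discarded and no thinning (tests and examples use shorter runs; the
acceptance script uses 2,000–4,000 iterations on 400–900-county lattices
to keep a full pipeline run to a few minutes on one CPU).

Numerical and design choices:

* **Priors.** $\beta \sim N(0, 10^6)$; every precision ($1/\sigma_u^2$,
  $1/\sigma_s^2$, each $1/\sigma_k^2$) has a Gamma(0.5, 0.0005) prior, a
  common vague disease-mapping default. All hyperparameters are exposed in
  `mcmc_config()`.
* **Initialisation.** Chain $c$ starts $\beta$ at the OLS estimate
  $\pm 2c$ standard errors (alternating sign) and the variances at 0.5 and
  2 times the method-of-moments residual variance, giving overdispersed
  starts for the Brooks–Gelman–Rubin diagnostic.
* **Identification.** $s$ is recentred to mean zero over non-island
  counties after every sweep. Counties with no neighbours (islands) have
  $s_i$ pinned at 0 and are excluded from the constraint and from the
  $\sigma_s^2$ update; this mirrors common practice with the WinBUGS-style
  `car.normal` construct, where the original analysis is silent.
* **Degeneracy guards.** Variance draws are floored at $10^{-12}$ (with a
  message when this triggers); non-finite draws abort with diagnostics.
  Disconnected graphs (beyond islands) are rejected: the intrinsic prior
  would then be rank-deficient beyond the single sum-to-zero constraint.
* **Convergence.** `bgr_diagnostic()` implements the split-chain potential
  scale reduction factor; `metric_report()` flags parameters above 1.1
  (the protocol names the diagnostic but no threshold; 1.1 is the
  conventional one).

## Environmental indicators

* `scale_unit()` — the $[0,1]$ min–max rescaling; idempotent and
  order-preserving; constant vectors are rejected.
* `concentration_score()` — the leading principal component
  (correlation-matrix PCA, since the five inputs have incommensurable
  units) of car commuting, public-transport commuting, walking/cycling
  commuting, post-1950 housing, and population density. The sign is fixed
  so car commuting loads negatively: strongly negative scores mark
  dispersed, car-dependent counties. Scores are standardised to unit
  variance. A vanishing gap between the two leading eigenvalues is
  reported as an error with the spectrum, since the component would then
  be arbitrary.
* `food_environment_index()` — the published index equally weights limited
  access to healthy foods and food insecurity on a 0–10 scale with 10 the
  best environment, but its exact normalisation is not public. The
  reconstruction here min–max scales each component over the cohort to a
  0–10 badness scale, averages them, and reverses. Pipelines that have a
  precomputed index column simply use it; the reconstruction exists so the
  generator and examples are self-contained.
* `quintile_assign()` — empirical 20/40/60/80 percentile cuts by default,
  with half-open lower-closed intervals (a county exactly at a cutpoint
  belongs to the higher quintile); published fixed cutpoints (e.g. the
  poverty breaks 11.8, 14.7, 18, 22.1) can be supplied to reproduce
  published table layouts. Ties that would empty a quintile are an error.

Descriptive tables (`crosstab_rates()`) use unweighted means of county
rates per cell: whether the original tables are population-weighted is not
stated, so unweighted is the default and a weight column is an explicit
option. Margins are plain means over the counties involved, so the "All"
cell always reconstructs the grand mean exactly.

## The synthetic generator

No real county data ship with the package; `simulate_county_data()`
generates datasets with the statistical structure the analysis assumes,
and retains the generating truth (never read by fitting code) for
recovery tests.

* **Geography.** A rook-contiguity lattice (queen optional) stands in for
  county adjacency; the default 30×30 = 900 counties keeps full fits to
  seconds while acceptance-scale runs use up to 50×50 = 2,500 (the real
  cohort is ~3,100 counties).
* **Indicators.** One latent standard-Gaussian field per variable, a
  50/50 variance mixture of a standardised ICAR draw and IID noise
  (lattice Moran's I around 0.3 — clustering is documented only
  qualitatively for the real indicators). The eight latent fields are
  whitened and mixed through the Cholesky factor of a fixed correlation
  matrix, so target cross-correlations are induced exactly in-sample;
  spatially autocorrelated fields would otherwise leave the realised
  correlations with sampling error several times the IID rate. The matrix
  fixes the two documented values — poverty–inactivity 0.48 and
  exercise-access–poverty −0.38 — and sets the remaining entries to mild
  plausible values (nearest-PSD repaired if needed). Measurement scales
  are anchored to published marginals: inactivity 25% ± 5, poverty
  16.5% ± 6.5 (its empirical quintile cutpoints then fall near the
  published 11.8/14.7/18/22.1), FEI 5.3 ± 1.3, with clipping to valid
  ranges.
* **Factors.** Census divisions are contiguous vertical lattice bands
  (spatially blocked, as real divisions are); urbanicity and majority
  ethnicity are multinomial draws at plausible US county frequencies;
  poverty quintiles are cut from the simulated poverty rate, which links
  them to the indicator fields and reproduces the poverty–environment
  confounding that drives the regression comparison.
* **Outcomes.** $y = X\beta_{\mathrm{true}} + s_{\mathrm{true}} + u$ for
  persons, males, and females, with sex-specific coefficient maps at the
  magnitudes of the published extended regression (e.g. inactivity slopes
  15.2/12.8/18.0 on the unit scale, concentration −16.5/−19.7/−13.8,
  small direct category effects), a shared ICAR field
  ($\sigma_s^2 = 4$ by default) and independent IID noise
  ($\sigma_u^2 = 1$). Because direct category effects are small while
  indicator effects are strong and poverty-linked, the default data are a
  *mediated* world: a categories-only regression shows a marked poverty
  gradient that the extended regression then largely explains away.
* `scenario_mediated()` sharpens this for the regression-comparison
  checks: indicator clustering share 0.8 and $\sigma_s^2 = 0.5$, so most
  residual clustering in the categories-only fit comes from the omitted
  indicators, and controlling them must raise percent explained, shrink
  the poverty coefficients, and reduce $\Lambda$.

What the generator does **not** emulate: BRFSS survey estimation error,
real county geography and population weights, dependence between the
categorical factors (e.g. division × urbanicity), or non-Gaussian rate
behaviour near the bounds. Passing recovery tests therefore show the
machinery is correct under the model's own assumptions, not that the
published coefficient values are reproduced — those depend on proprietary
compiled inputs and unreported prior/initialisation details.

## Simulating from the intrinsic prior

`simulate_spatial_effects()` draws from the ICAR distribution restricted
to the sum-to-zero subspace: with graph Laplacian $Q$ and non-null
eigenpairs $(\lambda_k, v_k)$, the draw is $\sigma_s \sum_k z_k
v_k/\sqrt{\lambda_k}$. On rook lattices the path-graph Laplacian has the
closed-form cosine eigenbasis, so the two-dimensional transform makes
draws on large lattices cheap; arbitrary graphs fall back to a dense
eigendecomposition. A draw's pairwise-difference quadratic form has
expectation $(n-1)\sigma_s^2$, which the tests verify by Monte Carlo.

## Known limitations

* Coefficient-level agreement with the published tables is out of reach by
  construction (no real data, unreported priors); the package's claims are
  properties: conditional/joint ICAR consistency, conjugate-posterior
  agreement, parameter recovery at nominal coverage, and the qualitative
  regression-comparison features.
* With strongly spatially structured regressors (division bands, clustered
  indicators), part of a realised spatial field is absorbed by the fixed
  effects — ordinary spatial confounding. Posterior-mean $\Lambda$ then
  deviates from the realised generating fraction by up to ±0.1 on single
  datasets even though pure intercept+spatial fits recover it almost
  exactly.
* The Gaussian likelihood ignores that rates live in [0, 100]; alternative
  spatial priors (proper CAR, BYM2, Leroux) and model comparison (DIC,
  WAIC) are out of scope.
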