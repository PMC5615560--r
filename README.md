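# countycar

Bayesian spatial regression for county-level obesity rates.

Obesity prevalence varies widely across US counties — by urban-rural
status, census division, area poverty, and majority race/ethnicity — and
much of that geographic variation is suspected to run through the
*obesogenic environment*: physical-activity access, the food environment,
and dispersed car-dependent settlement patterns. `countycar` re-implements
a county-level ecological analysis of this question as a reusable package,
for epidemiologists and spatial statisticians who want the full machinery
without the original proprietary data compilation: a Gaussian regression of
county rates with residual variation split between an IID component and a
spatially clustered component, plus the indicator construction, descriptive
geography tables, and a synthetic county generator that makes every claim
testable end-to-end.

## The model

For county *i* with observed risk factors `X_i`,

    y_i ~ N(X_i β + s_i, σ_u²)

with an intrinsic conditional autoregressive (ICAR) prior on the spatial
effects: `s_i | s_-i ~ N(mean of the L_i neighbouring effects, σ_s²/L_i)`,
identified by a sum-to-zero constraint. First-order interactions between
the four geographic categorisations are exchangeable random effects with
block variances. Two summary statistics are reported per fit:

* spatial fraction **Λ = var(s) / (var(s) + σ_u²)** — how much of the
  residual variation is spatially clustered (1 = fully clustered);
* **% variation explained** = 100·(1 − (var(s)+σ_u²)/var(y)).

Estimation is a from-scratch two-chain Gibbs sampler (C++ core, conjugate
full conditionals, overdispersed starts, split-chain Brooks–Gelman–Rubin
diagnostics). *Regression 1* uses the geographic categories and their six
interactions only; *Regression 2* adds seven unit-scaled environmental
indicators (leisure-time inactivity, adequate exercise access, the
fast-food/grocery outlet ratio, groceries per head, the 0–10 food
environment index, % fast-food restaurants, and a principal-component
"concentration" score of settlement/commuting patterns).

## Worked example

Generate a synthetic 20×20 county lattice under the mediated-confounding
scenario (environment effects strong and poverty-linked, direct category
effects small), then fit both regressions:

```r
library(countycar)

sim  <- simulate_county_data(scenario_mediated(seed = 1))
fit1 <- run_regression1(sim$data, sim$graph, mcmc_config(n_iter = 2000, seed = 301))
fit2 <- run_regression2(sim$data, sim$graph, mcmc_config(n_iter = 2000, seed = 601))

glance(fit2)
#> # A tibble: 1 × 8
#>       n n_chains n_draws sigma2_u sigma2_s lambda pct_explained max_rhat
#>   <int>    <int>   <int>    <dbl>    <dbl>  <dbl>         <dbl>    <dbl>
#> 1   400        2    2000     1.01    0.628  0.334          93.5     1.19

dplyr::filter(tidy(fit2), grepl("inactivity|concentration|poverty_q", term))
#> # A tibble: 6 × 5
#>   term                estimate conf.low conf.high  rhat
#>   <chr>                  <dbl>    <dbl>     <dbl> <dbl>
#> 1 poverty_q:2           0.0516  -0.370      0.473  1.00
#> 2 poverty_q:3           0.503    0.0308     0.933  1.01
#> 3 poverty_q:4           0.580    0.124      1.05   1.01
#> 4 poverty_q:5           0.789    0.230      1.34   1.02
#> 5 inactivity           15.9     14.7       17.0    1.03
#> 6 concentration_score -16.2    -17.5      -15.0    1.01
```

The inactivity slope (~16 on the unit scale: moving from the least to the
most inactive county adds ~16 percentage points of obesity) and the
negative concentration-score slope (compact, transit-oriented counties are
leaner) recover the generating magnitudes. Comparing the two regressions
shows the mediation pattern:

```r
compare_regressions(fit1, fit2)
#> # A tibble: 1 × 9
#>   pct_explained_1 pct_explained_2 delta_pct_explained lambda_1 lambda_2
#>             <dbl>           <dbl>               <dbl>    <dbl>    <dbl>
#> 1            25.5            93.5                68.0    0.726    0.334
#>   delta_lambda poverty_mean_abs_1 poverty_mean_abs_2 poverty_shrinkage
#>          <dbl>              <dbl>              <dbl>             <dbl>
#> 1       -0.392               3.58              0.481             0.866
```

Adding the environmental indicators raises explained variation from 26% to
94%, shrinks the poverty coefficients by ~87%, and cuts the spatially
structured share of residual variation from 0.73 to 0.33 — the environment
accounts for both the poverty gradient and most of the spatial clustering.
Descriptives work directly on the county table:

```r
quintile_profile(sim$data, "obesity_persons", "exercise_access")
#> # A tibble: 5 × 3
#>   quintile  mean     n
#>      <int> <dbl> <int>
#> 1        1  25.0    80
#> 2        2  23.0    80
#> 3        3  21.3    80
#> 4        4  19.9    80
#> 5        5  17.5    80

gradient_ratio(sim$data, "obesity_females", "poverty_q")  # 1.481
gradient_ratio(sim$data, "obesity_males", "poverty_q")    # 1.401
```

Obesity falls monotonically with exercise access, and the poverty gradient
is steeper for females than males, as in the real cohort.

## Adjacency files

Graphs read/write the GAL spatial-weights dialect and plain edge lists. A
4-node example (`inst/extdata/example4.gal`, a square `a–b`, `a–c`, `b–d`,
`c–d`):

```
4
a 2
b c
b 2
a d
c 2
a d
d 2
b c
```

```r
g <- read_graph_file(system.file("extdata", "example4.gal",
                                 package = "countycar"), "gal")
g$L
#> a b c d
#> 2 2 2 2
```

Edge lists are one `from to` pair per line; asymmetric input is
symmetrised with a warning, self-loops are errors. `grid_graph(rows, cols,
scheme)` builds rook/queen lattices directly.

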