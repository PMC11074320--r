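---
title: "Methods: inventory accounting and county-level downscaling of crop-farming emission intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inventory accounting and county-level downscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropcarbon)
```

## Scope and model

`cropcarbon` estimates county-level intensity of carbon emissions from crop
farming when direct county statistics do not exist. The chain is: an
activity-based provincial inventory, a random-forest screen of candidate
indicators, a random-forest downscaling regression applied to county proxy
covariates, and a multiplicative provincial mass-balance adjustment.

### Inventory

Emissions for a region-year are the sum over six activities — crop residue
open burning, rice cultivation, cropland emissions, machinery use, nitrogen
fertilizer production, pesticide production — of activity amount × emission
factor × GWP, summed over gases (CO₂, CH₄, N₂O). The accounting is linear in
the amounts, which the test suite exploits as an invariant. Emissions from
cropland change, peat drainage/burning and forest-product harvesting are out
of scope: their activity data carry large uncertainty and are deliberately
excluded from this accounting system.

Two configuration tables drive the step:

* **GWP table** (`default_gwp()`): CH₄ = 25, N₂O = 298, CO₂ = 1 — the AR4
  100-year convention, matching the era of the inventory literature this
  accounting follows. Both are plain data and overridable.
* **Emission-factor table** (`default_emission_factors()`): the shipped
  values are *illustrative placeholders* — unit-consistent and
  order-of-magnitude plausible, but not a published inventory's factors.
  Real studies must substitute factors appropriate to their region/period.
  The schema allows any (activity, gas) pairing because which gases each
  activity emits is itself inventory-specific.

Intensity is total emissions divided by land area, in t CO₂-eq/km²
throughout. Missing (region, year) rows are simply absent from output; no
interpolation is attempted.

### Indicator screening

All (province, year) rows are pooled into one regression of intensity on the
candidate per-area indicators; a random forest (500 trees, mtry = ⌊p/3⌋, the
regression convention; fixed recorded seed) supplies impurity-decrease
importances, rescaled to percent. Permutation importance is available via
`importance = "permutation"` (negative values are clamped at zero before
rescaling so the percent scale stays defined).

Selection takes the shortest importance-descending prefix whose cumulative
share reaches `cum_threshold` (default 0.95). This rule is a design choice:
published screens of this kind typically report the chosen set and its
cumulative share but not the rule; a cumulative threshold of 0.95 reproduces
the canonical worked example exactly (4 of 12 indicators, 95.76%
cumulative — see `select_indicators()` and the acceptance suite). Ties in
importance are broken lexicographically by indicator name so that selection
is deterministic. A boundary tolerance of 1e-9 on the cumulative comparison
keeps exact-threshold cases (e.g. equal shares) inclusive.

### Downscaling and the mass-balance constraint

The downscaling model is a random forest of provincial intensity on the
selected covariates, with diagnostics from three sources: the training set,
10-fold cross-validation (fold-mean R²/RMSE), and a 10% random hold-out. The
literature this design follows is ambiguous about its validation scheme — a
10% hold-out is described in the same breath as "leave-one-out" — so the
package implements the 90/10 split plus k-fold CV as primary and leaves
leave-one-out available as `cv_folds = nrow(train)`. The split uses
`round(test_frac * n)` rows, seeded; fold assignment is seeded independently.

County predictions are convex combinations of non-negative training
intensities, hence non-negative and range-bounded — a property tested
directly. Counties whose covariates are all zero receive whatever the forest
predicts; they are flagged with a warning rather than special-cased, since
no principled zero-rule exists.

The constraint is applied multiplicatively on emissions: within each
(province, year), `factor = E_prov / Σ_c raw_intensity × area`, and adjusted
intensity is `raw × factor`. Multiplicative scaling was chosen over additive
redistribution because it can never create negative intensities and it
preserves the within-province ranking of counties. Degenerate cases: a zero
provincial total sets all its counties to zero with factor 0; a zero raw sum
against a non-zero total is an error, since no multiplicative factor exists.
Conservation holds to machine precision; the tests assert 1e-6 relative as
the contract and observe ~1e-16.

Models are pooled over all years by default (one forest for the panel);
per-year models can be fit by filtering the input — the tables are ordinary
tibbles.

### Validation

`zonal_extract()` implements area-weighted mean aggregation of a gridded
field through an explicit cell-to-county weight table, replacing a GIS
polygon overlay with a testable contract (a GIS step can produce the weight
table once and reuse it). `compare_estimates()` reports Pearson r, the R² of
a linear fit, and mean bias over shared counties. The fit direction defaults
to reference-on-estimate; for a simple linear regression the R² equals r² in
either direction, so the choice only matters for slope-based diagnostics.
Pearson (not rank) correlation is used, matching the convention of
county-level comparisons against gridded reference products.

## The synthetic generator

`simulate_crop_world()` is a first-class module, not a test fixture: it
defines the study conditions under which the pipeline's claims are
verified.

* **Sizes.** Defaults are 15 provinces × 20 counties × 10 years — large
  enough that screening and downscaling behave like the real application
  (150 provincial training rows, 3 000 county-years), small enough that the
  full pipeline runs in seconds on one CPU. These sizes are also what the
  test suite and the acceptance script use.
* **Covariate fields.** The four informative per-area covariates
  (`population`, `rice_area`, `n_fertilizer`, `gpp` — mirroring the proxy
  set of the canonical 12-indicator screen) are log-normal with three
  variance layers: a persistent province effect (log-sd 0.2), a
  province-year shock shared by a province's counties (log-sd 0.5), and
  county-level deviations (log-sd 0.25). The province-year layer dominates
  deliberately: it gives the pooled provincial panel one effective
  observation per province-year rather than per province. With only
  persistent province effects, the screen's effective sample collapses to
  the number of provinces and nuisance indicators (which also have
  persistent province structure) can spuriously correlate with the target —
  a failure mode of the *design of a simulation*, not of the screening code.
  The same layered structure is used for the eight nuisance indicators,
  which are drawn independently of intensity.
* **Intensity link.** True county intensity is a monotone linear function
  of the informative covariates (coefficients 6, 5, 4, 3 plus intercept 2)
  times mean-one multiplicative log-normal noise with CV 0.05. Multiplicative
  log-normal noise keeps intensities strictly positive; CV 0.05 represents
  measurement-level noise on top of a strong structural signal. The
  coefficient spread makes all four informative indicators detectable while
  preserving a clear importance ordering.
* **Exact aggregation identities.** Province areas are the exact sums of
  county areas; provincial covariates are exact area-weighted county means;
  provincial activity amounts are back-derived through the EF/GWP tables so
  the inventory stage reproduces the provincial emission totals to numerical
  identity. Every downstream precondition is satisfied by construction, and
  regeneration from the same seed is bit-identical (tested on the CSV
  bytes).
* **Reference product.** True intensity times independent log-normal noise
  with CV 0.15, emulating an external gridded product resampled to
  counties.

What passing tests on this world do **not** show: realism of magnitudes
(the world is not calibrated to any national statistics), spatial
autocorrelation between neighbouring counties, covariate measurement error,
or proxy mismatch (the county proxies here are *perfect* proxies of the
provincial indicators — real satellite proxies are not). Recovery numbers on
synthetic data are therefore upper bounds on what identical settings would
achieve on real data.

## Numerical choices and observed performance

* Forests run single-threaded with a recorded seed; results are exactly
  reproducible (ranger's seeded RNG).
* Importance normalization tolerance: importances sum to 100 within 1e-6.
* Conservation contract: 1e-6 relative; observed ~1e-16 (a single
  multiplication per county).
* Zero-variance targets make R² undefined; `regression_metrics()` returns
  `NA` for R² while RMSE stays defined.
* At the default synthetic sizes the end-to-end pipeline recovers true
  county intensities with R² ≈ 0.88–0.92 across seeds (acceptance contract:
  ≥ 0.8), and the four informative indicators occupy the top four ranks in
  ≈ 94–100% of seeded runs (contract: ≥ 90%). With noise switched off
  recovery reaches ≈ 0.95; the remaining error is the forest's
  approximation beyond the provincial training support — counties more
  extreme than any province-year mean are clamped toward the training
  range, which the mass-balance adjustment only partly compensates.
* Fold-mean CV R² is biased below zero under a null (permuted-target)
  model, because each fold's R² penalizes prediction variance against the
  fold's own small variance; the suite asserts absence of positive skill
  rather than an exact zero.

## Limitations

* The EF defaults are placeholders; all quantitative claims in the tests
  use synthetic EF tables by design.
* The downscaler does not extrapolate beyond the range of provincial
  training intensities — county tails are compressed before adjustment.
* No uncertainty intervals accompany county estimates; the diagnostics
  quantify model fit, not prediction uncertainty.
* Gridded (sub-county) downscaling and GIS polygon processing are out of
  scope; zonal extraction expects a precomputed weight table.
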