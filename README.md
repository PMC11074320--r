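# cropcarbon

Activity-based greenhouse-gas inventory and random-forest downscaling of
crop-farming carbon emission intensity, from the provincial to the county
level.

National statistical yearbooks report agricultural activity data (fertilizer
use, rice area, machinery, residue burning, …) at the provincial level, while
mitigation policy is implemented by counties. `cropcarbon` implements the
full chain that bridges that gap, for analysts building county-scale emission
products from provincial statistics and satellite-derived proxy covariates:

1. **Inventory** — provincial CO₂-equivalent emissions from six crop-farming
   activities (crop residue open burning, rice cultivation, cropland
   emissions, machinery use, nitrogen fertilizer production, pesticide
   production), normalized to intensity per land area.
2. **Screening** — random-forest relative importance of candidate
   provincial indicators, with a cumulative-importance selection rule.
3. **Downscaling** — a random-forest regression of provincial intensity on
   the selected per-area covariates (90/10 train/test split, 10-fold CV),
   applied to county covariates.
4. **Mass-balance adjustment** — a per-province-year multiplicative factor
   forcing county emissions to sum exactly to the provincial inventory.
5. **Validation** — trend series, zonal extraction of gridded reference
   products, and county-level Pearson/R² comparisons.

A seeded synthetic-data generator (`simulate_crop_world()`) provides
province/county worlds with a known generative link, so the whole pipeline
is testable against ground truth without any external download.

## The model

For province $p$, year $t$ and activity $a$ with activity amount
$A_{p,t,a}$, the inventory is

$$E_{p,t} = \sum_a \sum_g A_{p,t,a}\; \mathrm{EF}_{a,g}\; \mathrm{GWP}_g ,
\qquad I_{p,t} = E_{p,t} / S_p ,$$

with $\mathrm{EF}_{a,g}$ the emission factor of gas $g$
($g \in \{\mathrm{CO_2}, \mathrm{CH_4}, \mathrm{N_2O}\}$),
$\mathrm{GWP}_g$ its 100-year global warming potential (defaults: CH₄ = 25,
N₂O = 298), $S_p$ the provincial land area, and $I$ the emission intensity
in t CO₂-eq/km². A random forest $\hat f$ is trained on
$(I_{p,t}, x_{p,t})$ where $x$ are the selected per-area indicators; county
intensity is $\hat I_{c,t} = \hat f(x_{c,t})$, then adjusted by

$$\lambda_{p,t} = \frac{E_{p,t}}{\sum_{c \in p} \hat I_{c,t} S_c},
\qquad I^{adj}_{c,t} = \lambda_{p,t}\, \hat I_{c,t},$$

so that $\sum_{c \in p} I^{adj}_{c,t} S_c = E_{p,t}$ exactly.

## Worked example

```r
library(cropcarbon)

w <- simulate_crop_world(seed = 42)   # 15 provinces x 20 counties x 10 years
res <- run_pipeline(w, seed = 42)
res
#> Crop-farming emission downscaling pipeline run
#>   provinces: 15   years: 10   counties: 300
#>   selected covariates: population, rice_area, gpp, n_fertilizer
#>   max mass-balance error: 2.16e-16
#>   recovery R2 vs truth: 0.915
#> # A tibble: 3 × 4
#>   dataset  r_squared  rmse     n
#>   <chr>        <dbl> <dbl> <int>
#> 1 training     0.941  1.66   135
#> 2 cv           0.756  3.25   135
#> 3 testing      0.655  5.76    15
```

The report says: the inventory's provincial totals were screened against 12
candidate indicators and the four informative ones were selected; the
downscaling forest explains 94% of training variance (76% under 10-fold
CV); after the mass-balance adjustment the county estimates reproduce the
provincial totals to machine precision and correlate with the generator's
true county intensities at R² = 0.915.

Individual stages compose with the pipe:

```r
provincial <- compute_emissions(w$activity_panel) |> to_intensity(w$areas)
report <- rank_indicators(w$indicators, seed = 42) |> select_indicators(0.95)
head(tibble::as_tibble(report), 4)
#> # A tibble: 4 × 5
#>   indicator     importance_pct  rank cumulative_pct selected
#>   <chr>                  <dbl> <int>          <dbl> <lgl>
#> 1 population             27.3      1           27.3 TRUE
#> 2 rice_area              25.1      2           52.4 TRUE
#> 3 gpp                    15.9      3           68.3 TRUE
#> 4 n_fertilizer            9.59     4           77.9 TRUE
```

`autoplot()` methods exist for importance reports and fitted downscalers;
`plot_national_series()` and `plot_county_comparison()` cover trend and
validation figures. `write_pipeline_outputs()` writes all result tables plus
a JSON run manifest; a thin command-line front-end is installed at
`inst/scripts/cropcarbon-cli.R`.

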