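# Shared fixtures and independent oracles for the test suite.

# The published 12-indicator relative-importance vector (percent).
table1_importances <- function() {
  tibble::tibble(
    indicator = c(
      "output of grain crops",
      "sown area of rice",
      "total population",
      "volume of effective component of nitrogenous fertilizer",
      "use of agricultural pesticide",
      "number of large animals",
      "number of sheep and goats",
      "total power of agricultural machinery",
      "number of large and medium-sized agricultural tractors",
      "number of small tractors",
      "gross output value of agriculture, forestry, animal husbandry and fishery",
      "gross output value of agriculture"
    ),
    importance_pct = c(2.40, 36.44, 50.32, 6.60, 1.13, 1.20,
                       0.25, 0.20, 0.32, 0.39, 0.27, 0.48)
  )
}

# A tiny two-activity EF table with known arithmetic, for forced examples.
toy_efs <- function() {
  tibble::tibble(
    activity = c("rice_cultivation", "machinery_use"),
    gas = c("CH4", "CO2"),
    ef = c(1.0, 0.5),
    unit = c("km2", "t fuel")
  )
}

# Random activity panel over a handful of regions/years/activities.
random_panel <- function(n_regions = 5, years = 2000:2002, seed = 1) {
  withr::with_seed(seed, {
    tidyr::expand_grid(
      region_id = sprintf("R%d", seq_len(n_regions)),
      year = years,
      activity = crop_activities()
    ) |>
      dplyr::mutate(amount = stats::runif(dplyr::n(), 0, 100))
  })
}

# Independent, deliberately naive triple-loop inventory oracle.
oracle_emissions <- function(panel, efs, gwps) {
  out <- panel[c("region_id", "year", "activity")]
  out$emissions_t <- NA_real_
  for (i in seq_len(nrow(panel))) {
    tot <- 0
    for (j in seq_len(nrow(efs))) {
      if (efs$activity[j] == panel$activity[i]) {
        for (k in seq_len(nrow(gwps))) {
          if (gwps$gas[k] == efs$gas[j]) {
            tot <- tot + panel$amount[i] * efs$ef[j] * gwps$gwp[k]
          }
        }
      }
    }
    out$emissions_t[i] <- tot
  }
  out[order(out$region_id, out$year, out$activity), ]
}

# Independent, loop-based R2 / RMSE oracle.
oracle_metrics <- function(obs, pred) {
  n <- length(obs)
  ss_res <- 0
  ss_tot <- 0
  se <- 0
  m <- sum(obs) / n
  for (i in seq_len(n)) {
    ss_res <- ss_res + (obs[i] - pred[i])^2
    ss_tot <- ss_tot + (obs[i] - m)^2
    se <- se + (obs[i] - pred[i])^2
  }
  list(
    r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
    rmse = sqrt(se / n)
  )
}

# Small synthetic world for fast tests.
small_world <- function(seed = 1, ...) {
  simulate_crop_world(
    n_provinces = 4, counties_per_province = 5, years = 2000:2003,
    seed = seed, ...
  )
}
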