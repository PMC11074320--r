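test_that("emissions are amount x EF x GWP summed over gases", {
  panel <- tibble::tibble(
    region_id = "R1", year = 2000,
    activity = c("machinery_use", "rice_cultivation"),
    amount = c(100, 10)
  )
  out <- compute_emissions(panel, toy_efs(), default_gwp())
  # CO2 at ef 0.5: 100 * 0.5 = 50; CH4 at ef 1 with GWP 25: 10 * 25 = 250
  expect_equal(
    out$emissions_t[out$activity == "machinery_use"], 50
  )
  expect_equal(
    out$emissions_t[out$activity == "rice_cultivation"], 250
  )

  zero <- compute_emissions(
    dplyr::mutate(panel, amount = 0), toy_efs(), default_gwp()
  )
  expect_true(all(zero$emissions_t == 0))
})

test_that("inventory rejects malformed panels and missing factors", {
  panel <- tibble::tibble(
    region_id = "R1", year = 2000, activity = "pesticide_production",
    amount = 5
  )
  expect_error(
    compute_emissions(panel, toy_efs()), "no emission-factor row.*pesticide"
  )
  expect_error(
    compute_emissions(dplyr::mutate(panel, amount = -1)), "negative"
  )
  dup <- dplyr::bind_rows(panel, panel)
  expect_error(compute_emissions(dup), "duplicate")
  ch4_panel <- dplyr::mutate(panel, activity = "rice_cultivation")
  expect_error(
    compute_emissions(ch4_panel, default_emission_factors(),
                      tibble::tibble(gas = "CO2", gwp = 1)),
    "no GWP.*CH4"
  )
})

test_that("compute_emissions is linear in the activity amounts", {
  efs <- default_emission_factors()
  a <- random_panel(seed = 11)
  b <- random_panel(seed = 22)
  mix <- dplyr::mutate(a, amount = 2 * a$amount + 3 * b$amount)
  out_mix <- compute_emissions(mix, efs)
  out_a <- compute_emissions(a, efs)
  out_b <- compute_emissions(b, efs)
  expect_equal(out_mix$emissions_t,
               2 * out_a$emissions_t + 3 * out_b$emissions_t,
               tolerance = 1e-12)
})

test_that("vectorized inventory matches the naive triple-loop oracle", {
  efs <- default_emission_factors()
  gwps <- default_gwp()
  for (seed in c(7, 19, 101)) {
    panel <- random_panel(n_regions = 5, seed = seed)
    got <- compute_emissions(panel, efs, gwps)
    want <- oracle_emissions(panel, efs, gwps)
    expect_equal(got$emissions_t, want$emissions_t, tolerance = 1e-12)
  }
})

test_that("intensity is total over area, with guarded areas", {
  em <- tibble::tibble(
    region_id = c("R1", "R2"), year = 2000,
    activity = "machinery_use", emissions_t = c(200, 0)
  )
  areas <- tibble::tibble(region_id = c("R1", "R2"), area_km2 = c(100, 50))
  rec <- to_intensity(em, areas)
  expect_equal(rec$intensity, c(2, 0))
  expect_equal(rec$total_t, c(200, 0))

  # doubling every area halves every intensity
  rec2 <- to_intensity(em, dplyr::mutate(areas, area_km2 = 2 * area_km2))
  expect_equal(rec2$intensity, rec$intensity / 2)

  expect_error(to_intensity(em, areas[1, ]), "no land area.*R2")
  expect_error(
    to_intensity(em, dplyr::mutate(areas, area_km2 = c(100, 0))),
    "positive"
  )
})

test_that("intensity is invariant under proportional region splitting", {
  # a region split into subregions with proportionally split totals and
  # areas keeps every subregion at the parent intensity
  em <- tibble::tibble(
    region_id = c("R1a", "R1b"), year = 2000,
    activity = "machinery_use", emissions_t = c(60, 140)
  )
  areas <- tibble::tibble(region_id = c("R1a", "R1b"),
                          area_km2 = c(30, 70))
  rec <- to_intensity(em, areas)
  expect_equal(rec$intensity, c(2, 2))
})

test_that("national series adds provinces and handles one year", {
  rec <- tibble::tibble(
    region_id = c("P1", "P2"), year = 2000,
    total_t = c(10, 20), area_km2 = c(5, 10), intensity = 2
  )
  nat <- national_series(rec)
  expect_equal(nrow(nat), 1)
  expect_equal(nat$total_t, 30)
  expect_equal(nat$mean_intensity, 2)

  # adding a province with positive emissions raises the national total
  rec3 <- dplyr::bind_rows(
    rec,
    tibble::tibble(region_id = "P3", year = 2000, total_t = 5,
                   area_km2 = 100, intensity = 0.05)
  )
  expect_gt(national_series(rec3)$total_t, nat$total_t)
})
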