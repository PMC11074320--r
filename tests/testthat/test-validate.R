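test_that("zonal extraction takes area-weighted county means", {
  # uniform field: every county inherits the constant
  grid <- tibble::tibble(cell_id = 1:9, value = 4.2)
  w <- tibble::tibble(
    cell_id = 1:9, county_id = rep(c("a", "b", "c"), each = 3), weight = 1
  )
  z <- zonal_extract(grid, w)
  expect_equal(z$value, rep(4.2, 3))

  # two equally-weighted cells of 2 and 4 average to 3
  z2 <- zonal_extract(
    tibble::tibble(cell_id = 1:2, value = c(2, 4)),
    tibble::tibble(cell_id = 1:2, county_id = "only", weight = 1)
  )
  expect_equal(z2$value, 3)

  # checkerboard 0/1: a county covering a 2x2 block averages 0.5
  chk <- tibble::tibble(cell_id = 1:4, value = c(0, 1, 1, 0))
  z3 <- zonal_extract(
    chk, tibble::tibble(cell_id = 1:4, county_id = "blk", weight = 2.5)
  )
  expect_equal(z3$value, 0.5)
})

test_that("zonal extraction warns on uncovered counties and errors when empty", {
  grid <- tibble::tibble(cell_id = 1:2, value = 1)
  w <- tibble::tibble(
    cell_id = c(1, 2, 99), county_id = c("a", "a", "ghost"), weight = 1
  )
  expect_warning(z <- zonal_extract(grid, w), "ghost")
  expect_equal(z$county_id, "a")

  none <- tibble::tibble(cell_id = 99, county_id = "ghost", weight = 1)
  expect_error(suppressWarnings(zonal_extract(grid, none)), "no county")
  expect_error(
    zonal_extract(grid, dplyr::mutate(w, weight = 0)), "positive"
  )
})

test_that("zonal extraction then aggregation preserves a constant field", {
  grid <- tibble::tibble(cell_id = 1:20, value = 7)
  w <- withr::with_seed(5, tibble::tibble(
    cell_id = 1:20,
    county_id = sample(c("a", "b", "c", "d"), 20, replace = TRUE),
    weight = runif(20, 0.1, 3)
  ))
  z <- zonal_extract(grid, w)
  expect_equal(mean(z$value), 7)
})

test_that("comparison statistics behave like Pearson correlation", {
  a <- tibble::tibble(county_id = letters[1:10], value = 1:10 + 0.5)
  self <- compare_estimates(a, a)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$r_squared, 1)
  expect_equal(self$bias, 0)

  b <- dplyr::mutate(a, value = -(value - mean(value)))
  anti <- compare_estimates(a, b)
  expect_equal(anti$pearson_r, -1)

  # r is symmetric in the two series and invariant to positive affine maps
  noisy <- withr::with_seed(2, dplyr::mutate(a, value = value + rnorm(10)))
  expect_equal(compare_estimates(a, noisy)$pearson_r,
               compare_estimates(noisy, a)$pearson_r)
  scaled <- dplyr::mutate(noisy, value = 3 * value + 40)
  expect_equal(compare_estimates(a, scaled)$pearson_r,
               compare_estimates(a, noisy)$pearson_r)

  expect_error(compare_estimates(a[1:2, ], a[1:2, ]), "fewer than 3")
  expect_error(
    compare_estimates(a, dplyr::mutate(a, value = 1)), "zero variance"
  )
})

test_that("the fit direction of the comparison R2 is configurable", {
  a <- tibble::tibble(county_id = letters[1:20], value = seq(1, 20))
  b <- withr::with_seed(3, dplyr::mutate(a, value = 2 * value + rnorm(20, 0, 4)))
  fwd <- compare_estimates(a, b, direction = "b_on_a")
  rev <- compare_estimates(a, b, direction = "a_on_b")
  # simple linear regression: R2 equals r^2 in both directions
  expect_equal(fwd$r_squared, fwd$pearson_r^2)
  expect_equal(rev$r_squared, rev$pearson_r^2)
})

test_that("a built-in linear national trend is recovered by OLS", {
  slope <- 50
  years <- 2000:2019
  rec <- withr::with_seed(21, tidyr::expand_grid(
    region_id = c("P1", "P2", "P3"), year = years
  ) |>
    dplyr::mutate(
      total_t = 1000 + slope / 3 * (year - 2000) + rnorm(60, 0, 20),
      area_km2 = 100
    ))
  nat <- national_series(rec)
  fit <- summary(lm(total_t ~ year, data = nat))
  est <- fit$coefficients["year", ]
  expect_lt(abs(est["Estimate"] - slope), 2 * est["Std. Error"])
})
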