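test_that("split_data partitions reproducibly at the requested fraction", {
  d <- tibble::tibble(id = 1:100, x = rnorm(100))
  parts <- split_data(d, test_frac = 0.1, seed = 4)
  expect_equal(nrow(parts$test), 10)
  expect_equal(nrow(parts$train), 90)
  expect_identical(parts, split_data(d, test_frac = 0.1, seed = 4))

  d20 <- tibble::tibble(id = 1:20)
  p20 <- split_data(d20, test_frac = 0.1, seed = 1)
  expect_equal(nrow(p20$test), 2)
  expect_equal(nrow(p20$train), 18)
  expect_setequal(c(p20$train$id, p20$test$id), d20$id)
  expect_length(intersect(p20$train$id, p20$test$id), 0)

  expect_error(split_data(d20[1:5, ]), "at least 10")
  expect_error(split_data(d, test_frac = 0), "0, 1")
  expect_error(split_data(d, test_frac = 1), "0, 1")
})

test_that("regression metrics match hand-computed values and edge cases", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$r_squared, 0.5)

  perfect <- regression_metrics(1:10, 1:10)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)

  obs <- c(2, 4, 6, 8)
  at_mean <- regression_metrics(obs, rep(mean(obs), 4))
  expect_equal(at_mean$r_squared, 0)

  flat <- regression_metrics(rep(3, 5), rnorm(5))
  expect_true(is.na(flat$r_squared))
  expect_gte(flat$rmse, 0)
})

test_that("evaluate matches an independently coded R2/RMSE formula", {
  withr::with_seed(99, {
    for (i in 1:25) {
      obs <- rnorm(50)
      pred <- obs + rnorm(50, sd = 0.5)
      got <- regression_metrics(obs, pred)
      want <- oracle_metrics(obs, pred)
      expect_equal(got$r_squared, want$r_squared, tolerance = 1e-12)
      expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
    }
  })
})

test_that("degenerate and noiseless regressions behave as expected", {
  d <- tibble::tibble(x = runif(50), intensity = 7)
  m <- fit_downscaler(d, "x", n_trees = 50, cv_folds = 5, seed = 1)
  expect_equal(unique(predict(m, d)), 7)
  expect_equal(m$diagnostics$rmse[m$diagnostics$dataset == "training"], 0)

  d2 <- withr::with_seed(8, tibble::tibble(x = runif(1000)))
  d2$intensity <- 3 * d2$x
  m2 <- fit_downscaler(d2, "x", n_trees = 200, cv_folds = 5, seed = 2)
  expect_gt(
    m2$diagnostics$r_squared[m2$diagnostics$dataset == "training"], 0.99
  )

  bad <- dplyr::mutate(d, x = replace(x, 3, NA))
  expect_error(fit_downscaler(bad, "x", seed = 1), "missing values")
})

test_that("a permuted target yields no cross-validated skill", {
  # fold-mean CV R2 under the null is biased somewhat below zero (each
  # fold's R2 penalizes the forest's prediction variance against the fold's
  # own variance); the scientific content is the absence of positive skill
  cv_r2 <- vapply(1:3, function(s) {
    d <- withr::with_seed(s, tibble::tibble(
      x1 = runif(200), x2 = runif(200), intensity = rnorm(200)
    ))
    dnull <- withr::with_seed(s + 100, dplyr::mutate(
      d, intensity = sample(intensity)
    ))
    m <- fit_downscaler(dnull, c("x1", "x2"), n_trees = 200,
                        cv_folds = 10, seed = s)
    m$diagnostics$r_squared[m$diagnostics$dataset == "cv"]
  }, numeric(1))
  expect_lt(mean(cv_r2), 0.15)
  expect_gt(mean(cv_r2), -0.6)
})

test_that("county predictions stay inside the training target range", {
  w <- small_world(seed = 3)
  m <- fit_downscaler(w$indicators, w$informative, n_trees = 100,
                      cv_folds = 5, seed = 3)
  est <- predict_counties(m, w$county_covariates)
  expect_true(all(est$raw_intensity >= min(w$indicators$intensity) - 1e-9))
  expect_true(all(est$raw_intensity <= max(w$indicators$intensity) + 1e-9))
  expect_true(all(est$raw_intensity >= 0))

  # identical covariate rows give identical predictions
  twice <- w$county_covariates[c(1, 1), ]
  twice$county_id <- c("a", "b")
  p <- predict_counties(m, twice)
  expect_equal(p$raw_intensity[1], p$raw_intensity[2])

  orphan <- dplyr::mutate(w$county_covariates, province_id = NA)
  expect_error(predict_counties(m, orphan), "province")
})

test_that("provincial adjustment closes the mass balance exactly", {
  est <- tibble::tibble(
    county_id = c("c1", "c2", "c3"), province_id = "P1", year = 2000,
    area_km2 = 10, raw_intensity = c(2, 3, 5)
  )
  prov <- tibble::tibble(region_id = "P1", year = 2000, total_t = 200)
  adj <- adjust_to_provincial(est, prov)
  expect_equal(adj$scaling_factor, rep(2, 3))
  expect_equal(adj$adjusted_intensity, c(4, 6, 10))

  # already-balanced estimates are untouched
  prov100 <- dplyr::mutate(prov, total_t = 100)
  adj1 <- adjust_to_provincial(est, prov100)
  expect_equal(adj1$scaling_factor, rep(1, 3))
  expect_equal(adj1$adjusted_intensity, est$raw_intensity)

  # zero provincial target zeroes the counties with factor 0
  adj0 <- adjust_to_provincial(est, dplyr::mutate(prov, total_t = 0))
  expect_equal(adj0$adjusted_intensity, rep(0, 3))
  expect_equal(adj0$scaling_factor, rep(0, 3))

  zero_raw <- dplyr::mutate(est, raw_intensity = 0)
  expect_error(adjust_to_provincial(zero_raw, prov), "zero raw")
  expect_error(
    adjust_to_provincial(est, dplyr::mutate(prov, year = 2001)),
    "no provincial total"
  )
})

test_that("adjustment conserves provincial totals on random fixtures", {
  for (seed in 1:20) {
    fix <- withr::with_seed(seed, {
      n_c <- 8
      tibble::tibble(
        county_id = sprintf("c%d", 1:n_c),
        province_id = rep(c("P1", "P2"), each = n_c / 2),
        year = 2000,
        area_km2 = runif(n_c, 10, 1000),
        raw_intensity = runif(n_c, 0.1, 50)
      )
    })
    prov <- withr::with_seed(seed + 1000, tibble::tibble(
      region_id = c("P1", "P2"), year = 2000,
      total_t = runif(2, 1e3, 1e6)
    ))
    adj <- adjust_to_provincial(fix, prov)
    sums <- adj |>
      dplyr::group_by(province_id) |>
      dplyr::summarise(s = sum(adjusted_intensity * area_km2))
    expect_equal(sums$s, prov$total_t, tolerance = 1e-9)
    # multiplicative scaling preserves within-province ranking
    ord <- adj |>
      dplyr::group_by(province_id) |>
      dplyr::summarise(same = identical(order(raw_intensity),
                                        order(adjusted_intensity)))
    expect_true(all(ord$same))
  }
})

test_that("model metadata and tidiers expose the fit schema", {
  w <- small_world(seed = 4)
  m <- fit_downscaler(w$indicators, w$informative, n_trees = 100,
                      cv_folds = 5, seed = 11)
  g <- glance(m)
  expect_equal(g$seed, 11)
  expect_equal(g$n_trees, 100)
  expect_lte(g$r_squared_train, 1)
  expect_gte(g$rmse_train, 0)
  td <- tidy(m)
  expect_setequal(td$covariate, w$informative)
  expect_equal(sum(td$importance_pct), 100)
})
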