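#' Random train/test split
#'
#' Randomly partitions rows into a training and testing set, reproducibly
#' for a given seed. The testing fraction follows the evaluation scheme of
#' the downscaling model: 10% of rows held out by default.
#'
#' @param data A data frame with at least 10 rows.
#' @param test_frac Fraction of rows in the testing set, in (0, 1); default
#'   0.1. The test size is `round(test_frac * n)`.
#' @param seed Integer seed controlling the partition.
#' @return A list with tibbles `train` and `test`; disjoint and together
#'   containing every input row.
#' @export
split_data <- function(data, test_frac = 0.1, seed = 1) {
  n <- nrow(data)
  if (!is.numeric(test_frac) || test_frac <= 0 || test_frac >= 1) {
    abort("`test_frac` must be in (0, 1)")
  }
  if (n < 10) abort("need at least 10 rows to split")
  n_test <- round(test_frac * n)
  if (n_test < 1 || n_test >= n) {
    abort("`test_frac` gives an empty train or test set")
  }
  idx <- withr::with_seed(seed, sample.int(n, n_test))
  list(
    train = as_tibble(data[-idx, , drop = FALSE]),
    test = as_tibble(data[idx, , drop = FALSE])
  )
}

#' Regression metrics: coefficient of determination and RMSE
#'
#' `R2 = 1 - SS_res / SS_tot` and `RMSE = sqrt(mean((obs - pred)^2))`. When
#' the observations have zero variance R2 is undefined and returned as `NA`
#' (RMSE is still reported).
#'
#' @param obs,pred Numeric vectors of equal length.
#' @return A tibble with columns `r_squared`, `rmse`, `n`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
regression_metrics <- function(obs, pred) {
  if (length(obs) != length(pred)) abort("`obs` and `pred` differ in length")
  if (length(obs) == 0) abort("empty input")
  if (anyNA(obs) || anyNA(pred)) abort("metrics undefined with missing values")
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  tibble::tibble(
    r_squared = r2,
    rmse = sqrt(mean((obs - pred)^2)),
    n = length(obs)
  )
}

#' Fit the random-forest downscaling model
#'
#' Fits a random-forest regression of regional emission intensity on the
#' selected per-area covariates, and records training-set and k-fold
#' cross-validation diagnostics (R2 and RMSE). The fitted object carries its
#' covariate schema so county-level prediction is guaranteed to use the same
#' columns in the same order.
#'
#' @param train Training rows: a data frame containing the target and all
#'   covariate columns. No missing values.
#' @param covariates Character vector of covariate column names (typically
#'   the `selected` set from [select_indicators()], mapped to their
#'   county-level proxies).
#' @param target Target column name (default `"intensity"`).
#' @param n_trees Number of trees (default 500).
#' @param mtry Covariates per split; default `max(1, floor(p / 3))`.
#' @param cv_folds Number of cross-validation folds (default 10; set to
#'   `nrow(train)` for leave-one-out).
#' @param seed Integer seed for forest and fold assignment.
#' @return A `downscaler` object: list with the fitted forest, `covariates`,
#'   `target`, fit metadata and a `diagnostics` tibble (one row per dataset:
#'   training and cross-validation).
#' @examples
#' w <- simulate_crop_world(n_provinces = 5, counties_per_province = 4,
#'                          years = 2000:2004, seed = 1)
#' m <- fit_downscaler(w$indicators, covariates = w$informative, seed = 1,
#'                     n_trees = 100, cv_folds = 5)
#' glance(m)
#' @export
fit_downscaler <- function(train, covariates, target = "intensity",
                           n_trees = 500, mtry = NULL, cv_folds = 10,
                           seed = 1) {
  if (nrow(train) == 0) abort("`train` is empty")
  miss <- setdiff(c(target, covariates), names(train))
  if (length(miss) > 0) {
    abort(paste0("column(s) not in `train`: ", paste(miss, collapse = ", ")))
  }
  m <- train[c(target, covariates)]
  if (anyNA(m)) {
    bad <- which(!stats::complete.cases(m))
    abort(paste0("missing values in rows: ",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (cv_folds < 2 || cv_folds > nrow(train)) {
    abort("`cv_folds` must be between 2 and nrow(train)")
  }
  if (is.null(mtry)) mtry <- max(1L, floor(length(covariates) / 3))

  x <- as.data.frame(m[covariates])
  y <- m[[target]]
  forest <- ranger::ranger(
    x = x, y = y, num.trees = n_trees, mtry = mtry,
    importance = "impurity", seed = seed, num.threads = 1
  )
  train_pred <- predict(forest, data = x, num.threads = 1)$predictions
  diag_train <- regression_metrics(y, train_pred) %>%
    mutate(dataset = "training", .before = 1)

  # k-fold CV: each fold held out once, forest refit on the rest
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(x))))
  cv <- purrr::map(seq_len(cv_folds), function(k) {
    fit_k <- ranger::ranger(
      x = x[folds != k, , drop = FALSE], y = y[folds != k],
      num.trees = n_trees, mtry = mtry, seed = seed + k, num.threads = 1
    )
    pred_k <- predict(fit_k, data = x[folds == k, , drop = FALSE],
                      num.threads = 1)$predictions
    regression_metrics(y[folds == k], pred_k)
  }) %>% bind_rows()
  diag_cv <- tibble::tibble(
    dataset = "cv",
    r_squared = mean(cv$r_squared),
    rmse = mean(cv$rmse),
    n = nrow(x)
  )

  structure(
    list(
      forest = forest,
      covariates = covariates,
      target = target,
      n_trees = n_trees,
      mtry = mtry,
      cv_folds = cv_folds,
      seed = seed,
      training_range = range(y),
      diagnostics = bind_rows(diag_train, diag_cv),
      cv_fold_metrics = cv
    ),
    class = "downscaler"
  )
}

#' Evaluate a downscaling model on held-out rows
#'
#' Pure function of the model and the rows: predicts the target for every
#' row and returns R2 and RMSE (see [regression_metrics()]).
#'
#' @param model A `downscaler` from [fit_downscaler()].
#' @param data Rows with the model's covariate and target columns.
#' @param dataset Label for the output row (default `"testing"`).
#' @return A one-row tibble: `dataset`, `r_squared`, `rmse`, `n`.
#' @export
evaluate_model <- function(model, data, dataset = "testing") {
  stopifnot(inherits(model, "downscaler"))
  if (nrow(data) == 0) abort("`data` is empty")
  miss <- setdiff(c(model$target, model$covariates), names(data))
  if (length(miss) > 0) {
    abort(paste0("column(s) missing: ", paste(miss, collapse = ", ")))
  }
  pred <- predict(model, data)
  regression_metrics(data[[model$target]], pred) %>%
    mutate(dataset = dataset, .before = 1)
}

#' @export
predict.downscaler <- function(object, newdata, ...) {
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss) > 0) {
    abort(paste0("covariate(s) missing from newdata: ",
                 paste(miss, collapse = ", ")))
  }
  x <- as.data.frame(newdata[object$covariates])
  if (anyNA(x)) abort("missing values in covariates")
  predict(object$forest, data = x, num.threads = 1)$predictions
}

#' Predict raw county-level emission intensity
#'
#' Applies the fitted downscaling model to county covariate rows. The raw
#' predictions are convex combinations of the (non-negative) training
#' intensities, so they are non-negative and bounded by the training range;
#' they do not yet satisfy the provincial mass balance — see
#' [adjust_to_provincial()].
#'
#' @param model A `downscaler`.
#' @param counties County covariates: `county_id`, `province_id`, `year`,
#'   `area_km2` (> 0) and the model's covariate columns. (county_id, year)
#'   keys must be unique and every county must carry its parent province.
#' @return A tibble `county_id`, `province_id`, `year`, `area_km2`,
#'   `raw_intensity` (t CO2-eq / km2).
#' @export
predict_counties <- function(model, counties) {
  stopifnot(inherits(model, "downscaler"))
  req <- c("county_id", "province_id", "year", "area_km2")
  miss <- setdiff(req, names(counties))
  if (length(miss) > 0) {
    abort(paste0("`counties` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(is.na(counties$province_id))) {
    abort("county rows without a province mapping")
  }
  if (any(counties$area_km2 <= 0)) abort("county areas must be positive")
  if (anyDuplicated(counties[c("county_id", "year")]) > 0) {
    abort("duplicate (county_id, year) keys")
  }
  cov0 <- rowSums(abs(as.data.frame(counties[model$covariates]))) == 0
  pred <- predict(model, counties)
  if (any(cov0 & pred > 0)) {
    warn(paste0(sum(cov0 & pred > 0),
                " county rows have all-zero covariates but positive",
                " predicted intensity"))
  }
  counties %>%
    as_tibble() %>%
    select(dplyr::all_of(req)) %>%
    mutate(raw_intensity = pred)
}

#' Enforce the provincial mass-balance constraint on county estimates
#'
#' Rescales raw county intensities multiplicatively so that, within each
#' (province, year), county emissions (intensity x area) sum exactly to the
#' provincial inventory total. The scaling is a single factor per
#' province-year, so it preserves the within-province ranking of counties.
#' A zero provincial total yields factor 0 (all counties set to zero); a
#' zero raw sum against a non-zero total is an error since no multiplicative
#' factor can close the balance.
#'
#' @param estimates Output of [predict_counties()]: `county_id`,
#'   `province_id`, `year`, `area_km2`, `raw_intensity`.
#' @param provincial Provincial emission records with `region_id`, `year`
#'   and `total_t` (e.g. from [to_intensity()]). Every (province, year) in
#'   `estimates` must have a total.
#' @return `estimates` with added `scaling_factor` and `adjusted_intensity`.
#' @examples
#' est <- tibble::tibble(
#'   county_id = c("c1", "c2", "c3"), province_id = "P1", year = 2000,
#'   area_km2 = 10, raw_intensity = c(2, 3, 5)
#' )
#' prov <- tibble::tibble(region_id = "P1", year = 2000, total_t = 200)
#' adjust_to_provincial(est, prov)
#' @export
adjust_to_provincial <- function(estimates, provincial) {
  req <- c("county_id", "province_id", "year", "area_km2", "raw_intensity")
  miss <- setdiff(req, names(estimates))
  if (length(miss) > 0) {
    abort(paste0("`estimates` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(c("region_id", "year", "total_t") %in% names(provincial))) {
    abort("`provincial` needs columns region_id, year, total_t")
  }
  if (any(estimates$raw_intensity < 0)) abort("raw intensities must be >= 0")

  prov <- provincial %>%
    select(province_id = "region_id", "year", "total_t")
  missing_keys <- estimates %>%
    distinct(.data$province_id, .data$year) %>%
    dplyr::anti_join(prov, by = c("province_id", "year"))
  if (nrow(missing_keys) > 0) {
    abort(paste0(
      "no provincial total for: ",
      paste(paste0(missing_keys$province_id, "/", missing_keys$year),
            collapse = ", ")
    ))
  }

  out <- estimates %>%
    as_tibble() %>%
    group_by(.data$province_id, .data$year) %>%
    mutate(raw_sum_t = sum(.data$raw_intensity * .data$area_km2)) %>%
    ungroup() %>%
    left_join(prov, by = c("province_id", "year"))

  bad <- out$raw_sum_t == 0 & out$total_t > 0
  if (any(bad)) {
    keys <- unique(paste0(out$province_id[bad], "/", out$year[bad]))
    abort(paste0("zero raw provincial sum with non-zero target for: ",
                 paste(keys, collapse = ", ")))
  }

  out %>%
    mutate(
      scaling_factor = dplyr::if_else(
        .data$total_t == 0, 0, .data$total_t / .data$raw_sum_t
      ),
      adjusted_intensity = .data$raw_intensity * .data$scaling_factor
    ) %>%
    select(-"raw_sum_t", -"total_t")
}

#' @export
print.downscaler <- function(x, ...) {
  cat("Random-forest downscaling model\n")
  cat("  target:    ", x$target, "\n", sep = "")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  trees: ", x$n_trees, "  mtry: ", x$mtry,
      "  cv folds: ", x$cv_folds, "  seed: ", x$seed, "\n", sep = "")
  print(x$diagnostics)
  invisible(x)
}

#' @rdname fit_downscaler
#' @param x,object A `downscaler`.
#' @param ... Unused.
#' @export
glance.downscaler <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    r_squared_train = d$r_squared[d$dataset == "training"],
    rmse_train = d$rmse[d$dataset == "training"],
    r_squared_cv = d$r_squared[d$dataset == "cv"],
    rmse_cv = d$rmse[d$dataset == "cv"],
    n = d$n[d$dataset == "training"],
    n_trees = x$n_trees,
    mtry = x$mtry,
    cv_folds = x$cv_folds,
    seed = x$seed
  )
}

#' @rdname fit_downscaler
#' @export
tidy.downscaler <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble::tibble(
    covariate = names(imp),
    importance = unname(imp),
    importance_pct = 100 * unname(imp) / sum(imp)
  ) %>%
    arrange(dplyr::desc(.data$importance))
}
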