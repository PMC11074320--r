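#' Run the full inventory-to-county pipeline
#'
#' Chains every stage on a synthetic world (or any object with the same
#' tables): activity-based inventory, intensity normalization, indicator
#' screening, the 90/10 split with k-fold cross-validated random-forest
#' downscaling, county prediction, provincial mass-balance adjustment, and
#' validation against the world's reference product and (for synthetic
#' worlds) the known truth.
#'
#' Only selected indicators that have a county-level proxy column are used
#' as model covariates, mirroring the fact that proxies exist only for the
#' important factors.
#'
#' @param world A `crop_world` from [simulate_crop_world()], or a list with
#'   the same tables (`activity_panel`, `areas`, `indicators`,
#'   `county_covariates`, optionally `truth` and `reference`).
#' @param efs,gwps Emission-factor and GWP tables for the inventory stage.
#' @param cum_threshold Cumulative-importance selection threshold (default
#'   0.95).
#' @param test_frac Held-out testing fraction (default 0.1).
#' @param n_trees,cv_folds Random-forest size and number of CV folds.
#' @param seed Integer seed for screening, split and model fit.
#' @return A `crop_pipeline` list: `provincial` (inventory records),
#'   `national` (trend series), `importance` (selection report), `model`
#'   (the fitted `downscaler`), `diagnostics` (training/CV/testing metrics),
#'   `estimates` (adjusted county intensities), `conservation` (per
#'   province-year relative mass-balance error), and — when truth/reference
#'   tables are present — `recovery` and `comparisons`.
#' @examples
#' w <- simulate_crop_world(n_provinces = 4, counties_per_province = 5,
#'                          years = 2000:2003, seed = 7)
#' res <- run_pipeline(w, n_trees = 100, cv_folds = 5, seed = 7)
#' res$diagnostics
#' @export
run_pipeline <- function(world,
                         efs = default_emission_factors(),
                         gwps = default_gwp(),
                         cum_threshold = 0.95,
                         test_frac = 0.1,
                         n_trees = 500,
                         cv_folds = 10,
                         seed = 1) {
  # 1. inventory: activity amounts -> CO2-eq totals -> intensity
  emissions <- compute_emissions(world$activity_panel, efs, gwps)
  provincial <- to_intensity(emissions, world$areas)
  national <- national_series(provincial)

  # 2. screening on the pooled provincial panel, target from the inventory
  indicator_cols <- setdiff(names(world$indicators),
                            c("region_id", "year", "intensity"))
  screen_data <- world$indicators %>%
    select("region_id", "year", dplyr::all_of(indicator_cols)) %>%
    inner_join(provincial[c("region_id", "year", "intensity")],
               by = c("region_id", "year"))
  importance <- rank_indicators(
    screen_data, target = "intensity", indicators = indicator_cols,
    n_trees = n_trees, seed = seed
  ) %>%
    select_indicators(cum_threshold = cum_threshold)

  selected <- importance$indicator[importance$selected]
  covariates <- intersect(selected, names(world$county_covariates))
  if (length(covariates) == 0) {
    abort("no selected indicator has a county-level proxy column")
  }
  if (length(covariates) < length(selected)) {
    warn(paste0("selected indicator(s) without county proxy dropped: ",
                paste(setdiff(selected, covariates), collapse = ", ")))
  }

  # 3. downscaling model on provincial rows: 90/10 split + k-fold CV
  model_data <- screen_data %>%
    select("region_id", "year", "intensity", dplyr::all_of(covariates))
  parts <- split_data(model_data, test_frac = test_frac, seed = seed)
  model <- fit_downscaler(
    parts$train, covariates = covariates, target = "intensity",
    n_trees = n_trees, cv_folds = cv_folds, seed = seed
  )
  diagnostics <- bind_rows(
    model$diagnostics,
    evaluate_model(model, parts$test, dataset = "testing")
  )

  # 4. county prediction + provincial mass-balance constraint
  estimates <- predict_counties(model, world$county_covariates) %>%
    adjust_to_provincial(provincial)

  conservation <- estimates %>%
    group_by(.data$province_id, .data$year) %>%
    summarise(
      county_sum_t = sum(.data$adjusted_intensity * .data$area_km2),
      .groups = "drop"
    ) %>%
    inner_join(
      provincial %>% select(province_id = "region_id", "year", "total_t"),
      by = c("province_id", "year")
    ) %>%
    mutate(rel_error = abs(.data$county_sum_t - .data$total_t) /
             ifelse(.data$total_t == 0, 1, .data$total_t))

  out <- list(
    provincial = provincial,
    national = national,
    importance = importance,
    model = model,
    diagnostics = diagnostics,
    estimates = estimates,
    conservation = conservation,
    config = list(
      cum_threshold = cum_threshold, test_frac = test_frac,
      n_trees = n_trees, cv_folds = cv_folds, seed = seed,
      covariates = covariates
    )
  )

  # 5. validation against ground truth / reference product, when available
  if (!is.null(world$truth)) {
    joined <- estimates %>%
      inner_join(
        world$truth[c("county_id", "year", "true_intensity")],
        by = c("county_id", "year")
      )
    out$recovery <- regression_metrics(joined$true_intensity,
                                       joined$adjusted_intensity)
  }
  if (!is.null(world$reference)) {
    yrs <- sort(unique(estimates$year))
    out$comparisons <- purrr::map(yrs, function(y) {
      compare_estimates(
        estimates %>% filter(.data$year == y) %>%
          select("county_id", value = "adjusted_intensity"),
        world$reference %>% filter(.data$year == y) %>%
          select("county_id", "value"),
        name = "synthetic reference", year = y
      )
    }) %>% bind_rows()
  }

  structure(out, class = "crop_pipeline")
}

#' @export
print.crop_pipeline <- function(x, ...) {
  cat("Crop-farming emission downscaling pipeline run\n")
  cat("  provinces: ", dplyr::n_distinct(x$provincial$region_id),
      "   years: ", dplyr::n_distinct(x$provincial$year),
      "   counties: ", dplyr::n_distinct(x$estimates$county_id),
      "\n", sep = "")
  cat("  selected covariates: ",
      paste(x$config$covariates, collapse = ", "), "\n", sep = "")
  cat("  max mass-balance error: ",
      format(max(x$conservation$rel_error), digits = 3), "\n", sep = "")
  if (!is.null(x$recovery)) {
    cat("  recovery R2 vs truth: ",
        sprintf("%.3f", x$recovery$r_squared), "\n", sep = "")
  }
  print(x$diagnostics)
  invisible(x)
}

#' Write pipeline results and a run manifest to a directory
#'
#' Writes the provincial records, importance report, county estimates (long
#' and county-by-year wide layouts), diagnostics and any comparison tables
#' as CSV, plus a JSON manifest recording the configuration, seed, file
#' digests and timestamp, so a run can be audited and re-executed.
#'
#' @param result A `crop_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the manifest file.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "crop_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list(
    provincial_emissions = result$provincial,
    national_series = result$national,
    importance_report = as_tibble(result$importance),
    model_diagnostics = result$diagnostics,
    county_estimates = result$estimates,
    conservation_check = result$conservation
  )
  if (!is.null(result$comparisons)) files$comparisons <- result$comparisons
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(files[[nm]], p)
    paths[nm] <- p
  }
  paths["county_matrix"] <- file.path(dir, "county_matrix.csv")
  write_county_matrix(result$estimates, paths[["county_matrix"]])

  manifest_path <- file.path(dir, "run_manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("cropcarbon")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = result$config,
    files = as.list(unname(paths)),
    digests = as.list(tools::md5sum(unname(paths)))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest_path)
}
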