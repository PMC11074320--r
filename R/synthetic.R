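#' Simulate a synthetic province/county world with known ground truth
#'
#' Generates a seeded synthetic counterpart of the pipeline's inputs —
#' provincial activity statistics, a provincial indicator matrix, county
#' covariates, and a noisy reference product — with a fully known
#' province-to-county generative link, so that every stage of the pipeline
#' can be validated against ground truth.
#'
#' The generative model:
#' * County land areas are log-normal; a province's land area is the exact
#'   sum of its counties' areas.
#' * Four informative per-area covariates (`population`, `rice_area`,
#'   `n_fertilizer`, `gpp`) are log-normal fields with three variance
#'   layers: a persistent province effect (log-sd `sd_between`), a
#'   province-year shock shared by a province's counties (log-sd
#'   `sd_year`), and within-province county deviations (log-sd
#'   `sd_within`). Province-year variation dominates, so the pooled
#'   provincial panel carries one effective observation per province-year
#'   rather than per province, and provincial (area-weighted mean)
#'   covariates span the same range counties do — the premise of training
#'   at the provincial level and predicting at the county level.
#' * True county intensity is a monotone linear function of the informative
#'   covariates (coefficients in `beta`), times multiplicative log-normal
#'   noise with coefficient of variation `noise_cv` (default 0.05; the
#'   log-normal is mean-one so noise adds no systematic bias).
#' * Provincial indicator aggregates are the exact area-weighted means of
#'   county covariates; eight nuisance indicators (mirroring the structure
#'   of a 12-indicator candidate screen) are drawn independently of
#'   intensity.
#' * Provincial activity amounts are back-derived from the provincial
#'   emission totals (the sum of true county emissions) through the
#'   emission-factor and GWP tables, so the inventory stage reproduces the
#'   provincial totals exactly.
#' * The reference product is true county intensity times independent
#'   log-normal noise with CV `reference_cv` (default 0.15).
#'
#' @param n_provinces Number of provinces (default 15; must be >= 2).
#' @param counties_per_province Counties per province (default 20; >= 2).
#' @param years Integer vector of calendar years (default 2000:2009; length
#'   >= 2).
#' @param noise_cv Coefficient of variation of the multiplicative noise on
#'   true county intensity (default 0.05).
#' @param reference_cv CV of the independent noise in the reference product
#'   (default 0.15).
#' @param sd_between,sd_year,sd_within Log-scale standard deviations of the
#'   covariate fields: persistent province effect, province-year shock
#'   (year-to-year variation shared by a province's counties), and
#'   within-province county deviation.
#' @param beta Named coefficients of the linear intensity link; the
#'   intercept is `beta0`.
#' @param beta0 Intercept of the intensity link (t CO2-eq / km2).
#' @param efs,gwps Emission-factor and GWP tables used to back-derive
#'   activity amounts.
#' @param seed Integer seed; regeneration with the same seed and parameters
#'   is bit-identical.
#' @return A `crop_world` list with tibbles `activity_panel`, `areas`
#'   (provincial), `indicators` (provincial matrix: 12 indicator columns
#'   plus `intensity` target), `county_covariates`, `truth` (true county
#'   intensities), `reference`, `provincial` (inventory-consistent totals
#'   and intensity), character vectors `informative` and `nuisance`, and
#'   `params` echoing every generator parameter.
#' @examples
#' w <- simulate_crop_world(n_provinces = 3, counties_per_province = 4,
#'                          years = 2000:2002, seed = 42)
#' w$provincial
#' @export
simulate_crop_world <- function(n_provinces = 15,
                                counties_per_province = 20,
                                years = 2000:2009,
                                noise_cv = 0.05,
                                reference_cv = 0.15,
                                sd_between = 0.2,
                                sd_year = 0.5,
                                sd_within = 0.25,
                                beta = c(population = 6, rice_area = 5,
                                         n_fertilizer = 4, gpp = 3),
                                beta0 = 2,
                                efs = default_emission_factors(),
                                gwps = default_gwp(),
                                seed = 1) {
  if (n_provinces < 2) abort("need at least 2 provinces")
  if (counties_per_province < 2) abort("need at least 2 counties per province")
  years <- as.integer(years)
  if (length(years) < 2) abort("need at least 2 years")
  if (noise_cv < 0 || reference_cv < 0) abort("noise CVs must be >= 0")
  informative <- names(beta)
  if (length(informative) == 0 || is.null(informative)) {
    abort("`beta` must be a named coefficient vector")
  }
  if (any(beta < 0) || beta0 < 0) {
    abort("intensity link must be monotone non-decreasing: beta, beta0 >= 0")
  }
  check_ef_table(efs)
  check_gwp_table(gwps)
  nuisance <- c(
    "pesticide_use", "large_animals", "sheep_goats", "machinery_power",
    "large_tractors", "small_tractors", "agri_output_value",
    "farming_output_value"
  )

  withr::with_seed(seed, {
    provinces <- sprintf("P%02d", seq_len(n_provinces))
    counties <- tibble::tibble(
      province_id = rep(provinces, each = counties_per_province),
      county_id = sprintf(
        "%s_C%02d",
        rep(provinces, each = counties_per_province),
        rep(seq_len(counties_per_province), times = n_provinces)
      ),
      area_km2 = rlnorm(n_provinces * counties_per_province,
                        meanlog = log(500), sdlog = 0.4)
    )
    areas <- counties %>%
      group_by(region_id = .data$province_id) %>%
      summarise(area_km2 = sum(.data$area_km2), .groups = "drop")

    # informative covariate fields: province effect + county deviation,
    # plus a mild common year trend so the panel is a genuine time series
    prov_eff <- matrix(
      rnorm(n_provinces * length(informative), 0, sd_between),
      n_provinces, length(informative),
      dimnames = list(provinces, informative)
    )
    year_trend <- stats::approx(
      x = range(years), y = c(0, 0.15), xout = years
    )$y
    names(year_trend) <- as.character(years)

    grid <- tidyr::expand_grid(
      counties[c("province_id", "county_id", "area_km2")],
      year = years
    )
    n_cy <- nrow(grid)
    py_key <- paste(grid$province_id, grid$year)
    py_levels <- unique(py_key)
    for (v in informative) {
      # province-year shock shared by all counties of a province that year
      py_shock <- setNames(rnorm(length(py_levels), 0, sd_year), py_levels)
      grid[[v]] <- rlnorm(
        n_cy,
        meanlog = prov_eff[grid$province_id, v] +
          year_trend[as.character(grid$year)] +
          py_shock[py_key],
        sdlog = sd_within
      )
    }

    # monotone linear intensity link + mean-one multiplicative noise
    sig <- sqrt(log(1 + noise_cv^2))
    link <- beta0 +
      as.matrix(grid[informative]) %*% beta[informative]
    grid$true_intensity <- as.numeric(link) *
      rlnorm(n_cy, meanlog = -sig^2 / 2, sdlog = sig)

    truth <- grid %>%
      select("county_id", "province_id", "year", "area_km2",
             "true_intensity")
    county_covariates <- grid %>%
      select("county_id", "province_id", "year", "area_km2",
             dplyr::all_of(informative))

    # provincial panel: exact area-weighted aggregation of counties
    provincial <- grid %>%
      group_by(region_id = .data$province_id, .data$year) %>%
      summarise(
        total_t = sum(.data$true_intensity * .data$area_km2),
        dplyr::across(
          dplyr::all_of(informative),
          ~ sum(.x * area_km2) / sum(area_km2)
        ),
        .groups = "drop"
      ) %>%
      inner_join(areas, by = "region_id") %>%
      mutate(intensity = .data$total_t / .data$area_km2)

    # nuisance indicators: provincial, independent of intensity
    nuis_eff <- matrix(
      rnorm(n_provinces * length(nuisance), 0, sd_between),
      n_provinces, length(nuisance), dimnames = list(provinces, nuisance)
    )
    for (v in nuisance) {
      # same province-effect + province-year variance structure as the
      # informative fields, but independent of intensity by construction
      provincial[[v]] <- rlnorm(
        nrow(provincial),
        meanlog = nuis_eff[provincial$region_id, v] +
          rnorm(nrow(provincial), 0, sd_year),
        sdlog = sd_within
      )
    }
    indicators <- provincial %>%
      select("region_id", "year", "intensity",
             dplyr::all_of(c(informative, nuisance)))

    # back-derive activity amounts so the inventory reproduces the totals
    co2eq <- efs %>%
      inner_join(gwps, by = "gas") %>%
      group_by(.data$activity) %>%
      summarise(k = sum(.data$ef * .data$gwp), .groups = "drop")
    shares <- tibble::tibble(
      activity = crop_activities(),
      share = c(0.10, 0.30, 0.25, 0.10, 0.20, 0.05)
    )
    activity_panel <- provincial %>%
      select("region_id", "year", "total_t") %>%
      tidyr::expand_grid(shares) %>%
      inner_join(co2eq, by = "activity") %>%
      mutate(amount = .data$total_t * .data$share / .data$k) %>%
      select("region_id", "year", "activity", "amount")

    # independent noisy reference product
    sig_ref <- sqrt(log(1 + reference_cv^2))
    reference <- truth %>%
      mutate(value = .data$true_intensity *
               rlnorm(nrow(truth), -sig_ref^2 / 2, sig_ref)) %>%
      select("county_id", "province_id", "year", "value")

    structure(
      list(
        activity_panel = activity_panel,
        areas = areas,
        indicators = indicators,
        county_covariates = county_covariates,
        truth = truth,
        reference = reference,
        provincial = provincial %>%
          select("region_id", "year", "total_t", "area_km2", "intensity"),
        informative = informative,
        nuisance = nuisance,
        params = list(
          seed = seed, n_provinces = n_provinces,
          counties_per_province = counties_per_province,
          years = years, noise_cv = noise_cv, reference_cv = reference_cv,
          sd_between = sd_between, sd_year = sd_year,
          sd_within = sd_within,
          beta = beta, beta0 = beta0
        )
      ),
      class = "crop_world"
    )
  })
}

#' @export
print.crop_world <- function(x, ...) {
  p <- x$params
  cat("Synthetic crop-farming world (seed ", p$seed, ")\n", sep = "")
  cat("  ", p$n_provinces, " provinces x ", p$counties_per_province,
      " counties x ", length(p$years), " years (",
      min(p$years), "-", max(p$years), ")\n", sep = "")
  cat("  intensity noise CV ", p$noise_cv,
      ", reference noise CV ", p$reference_cv, "\n", sep = "")
  cat("  informative: ", paste(x$informative, collapse = ", "), "\n", sep = "")
  cat("  nuisance:    ", paste(x$nuisance, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to CSV files plus a JSON manifest
#'
#' Writes every table of a [simulate_crop_world()] result in the CSV
#' dialects the pipeline stages read, together with a manifest recording
#' all generator parameters and the seed.
#'
#' @param world A `crop_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_crop_world <- function(world, dir) {
  stopifnot(inherits(world, "crop_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("activity_panel", "areas", "indicators", "county_covariates",
              "truth", "reference", "provincial")
  paths <- setNames(file.path(dir, paste0(tables, ".csv")), tables)
  for (t in tables) readr::write_csv(world[[t]], paths[[t]])
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    c(world$params,
      list(informative = world$informative, nuisance = world$nuisance,
           files = as.list(paths))),
    manifest,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(paths, manifest = manifest))
}
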