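#' Compute CO2-equivalent emissions from an activity panel
#'
#' The inventory step: for every (region, year, activity) row, emissions in
#' tons CO2-eq are `amount x ef(activity, gas) x gwp(gas)` summed over the
#' gases that activity emits. Regions are typically provinces but the
#' accounting is agnostic to the administrative level.
#'
#' @param panel A data frame with columns `region_id`, `year`, `activity`,
#'   `amount`. Amounts must be non-negative and expressed in the unit the EF
#'   table declares for that activity; (region_id, year, activity) keys must
#'   be unique.
#' @param efs Emission-factor table with columns `activity`, `gas`, `ef`
#'   (see [default_emission_factors()]). Every activity present in `panel`
#'   must have at least one EF row.
#' @param gwps GWP table with columns `gas`, `gwp` (see [default_gwp()]).
#' @return A tibble with one row per (region_id, year, activity):
#'   `emissions_t` in tons CO2-eq.
#' @examples
#' panel <- tibble::tibble(
#'   region_id = "P1", year = 2000,
#'   activity = "rice_cultivation", amount = 120
#' )
#' compute_emissions(panel)
#' @seealso [to_intensity()] to aggregate to totals and normalize by area.
#' @export
compute_emissions <- function(panel,
                              efs = default_emission_factors(),
                              gwps = default_gwp()) {
  req <- c("region_id", "year", "activity", "amount")
  miss <- setdiff(req, names(panel))
  if (length(miss) > 0) {
    abort(paste0("activity panel lacks column(s): ", paste(miss, collapse = ", ")))
  }
  check_ef_table(efs)
  check_gwp_table(gwps)

  if (any(is.na(panel$amount)) || any(panel$amount < 0)) {
    bad <- unique(panel$activity[is.na(panel$amount) | panel$amount < 0])
    abort(paste0("negative or missing amounts for activity: ",
                 paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(panel[c("region_id", "year", "activity")]) > 0) {
    abort("duplicate (region_id, year, activity) keys in activity panel")
  }
  no_ef <- setdiff(unique(panel$activity), unique(efs$activity))
  if (length(no_ef) > 0) {
    abort(paste0("no emission-factor row for activity: ",
                 paste(no_ef, collapse = ", ")))
  }
  no_gwp <- setdiff(unique(efs$gas[efs$activity %in% panel$activity]), gwps$gas)
  if (length(no_gwp) > 0) {
    abort(paste0("no GWP entry for gas: ", paste(no_gwp, collapse = ", ")))
  }

  # CO2-eq factor per activity: sum over gases of ef * gwp
  co2eq <- efs %>%
    inner_join(gwps, by = "gas") %>%
    group_by(.data$activity) %>%
    summarise(co2eq_per_unit = sum(.data$ef * .data$gwp), .groups = "drop")

  panel %>%
    as_tibble() %>%
    inner_join(co2eq, by = "activity") %>%
    mutate(emissions_t = .data$amount * .data$co2eq_per_unit) %>%
    select("region_id", "year", "activity", "emissions_t") %>%
    arrange(.data$region_id, .data$year, .data$activity)
}

#' Aggregate activity emissions and normalize to intensity per land area
#'
#' Sums per-activity CO2-eq emissions to a regional total and divides by the
#' region's land area, giving emission intensity in tons CO2-eq per km2 —
#' the unit in which all downstream screening and downscaling operates.
#'
#' @param emissions Output of [compute_emissions()]: a data frame with
#'   `region_id`, `year`, `emissions_t` (activity-level rows).
#' @param areas A data frame with `region_id` and `area_km2` (> 0). Every
#'   region present in `emissions` must appear here.
#' @return A tibble with one row per (region_id, year): `total_t` (tons
#'   CO2-eq), `area_km2` and `intensity` (t CO2-eq / km2).
#' @examples
#' panel <- tibble::tibble(
#'   region_id = "P1", year = 2000,
#'   activity = "pesticide_production", amount = 10
#' )
#' areas <- tibble::tibble(region_id = "P1", area_km2 = 90)
#' compute_emissions(panel) |> to_intensity(areas)
#' @export
to_intensity <- function(emissions, areas) {
  if (!all(c("region_id", "year", "emissions_t") %in% names(emissions))) {
    abort("`emissions` needs columns region_id, year, emissions_t")
  }
  if (!all(c("region_id", "area_km2") %in% names(areas))) {
    abort("`areas` needs columns region_id, area_km2")
  }
  totals <- emissions %>%
    group_by(.data$region_id, .data$year) %>%
    summarise(total_t = sum(.data$emissions_t), .groups = "drop")

  no_area <- setdiff(unique(totals$region_id), areas$region_id)
  if (length(no_area) > 0) {
    abort(paste0("no land area for region: ", paste(no_area, collapse = ", ")))
  }
  if (any(is.na(areas$area_km2)) || any(areas$area_km2 <= 0)) {
    abort("land areas must be positive")
  }

  totals %>%
    inner_join(areas[c("region_id", "area_km2")], by = "region_id") %>%
    mutate(intensity = .data$total_t / .data$area_km2) %>%
    arrange(.data$region_id, .data$year)
}

#' National (or multi-region) time series of emissions and mean intensity
#'
#' Aggregates regional emission records to a single series per year: total
#' emissions summed over regions and mean intensity as total emissions over
#' total land area. Used for trend diagnostics of the inventory.
#'
#' @param records Output of [to_intensity()]: columns `region_id`, `year`,
#'   `total_t`, `area_km2`.
#' @return A tibble with one row per year: `total_t`, `area_km2`,
#'   `mean_intensity`.
#' @export
national_series <- function(records) {
  req <- c("region_id", "year", "total_t", "area_km2")
  if (!all(req %in% names(records))) {
    abort("`records` needs columns region_id, year, total_t, area_km2")
  }
  records %>%
    group_by(.data$year) %>%
    summarise(
      total_t = sum(.data$total_t),
      area_km2 = sum(.data$area_km2),
      .groups = "drop"
    ) %>%
    mutate(mean_intensity = .data$total_t / .data$area_km2) %>%
    arrange(.data$year)
}
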