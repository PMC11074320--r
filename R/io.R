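# CSV readers/writers for the pipeline's table contracts. All readers
# validate the column schema up front so a stage fails at load, not mid-run.

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    abort(paste0(path, " lacks column(s): ", paste(miss, collapse = ", ")))
  }
  x
}

#' Read pipeline input tables from CSV
#'
#' Readers for the pipeline's tabular inputs, each validating its column
#' contract: `read_activity_panel()` expects `region_id, year, activity,
#' amount`; `read_areas()` expects `region_id, area_km2`;
#' `read_indicator_matrix()` expects `region_id, year` plus the target and
#' indicator columns; `read_county_covariates()` expects `county_id,
#' province_id, year, area_km2` plus covariate columns.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble.
#' @name pipeline-io
#' @export
read_activity_panel <- function(path) {
  read_checked_csv(path, c("region_id", "year", "activity", "amount"))
}

#' @rdname pipeline-io
#' @export
read_areas <- function(path) {
  read_checked_csv(path, c("region_id", "area_km2"))
}

#' @rdname pipeline-io
#' @export
read_indicator_matrix <- function(path) {
  read_checked_csv(path, c("region_id", "year"))
}

#' @rdname pipeline-io
#' @export
read_county_covariates <- function(path) {
  read_checked_csv(path, c("county_id", "province_id", "year", "area_km2"))
}

#' Write county estimates as a county-by-year intensity table
#'
#' Pivots adjusted county intensities to the published layout: one row per
#' county, one column per year. Also useful for eyeballing trends.
#'
#' @param estimates Output of [adjust_to_provincial()].
#' @param path Destination CSV path; if `NULL` the wide tibble is returned
#'   without writing.
#' @return The wide tibble, invisibly when written.
#' @export
write_county_matrix <- function(estimates, path = NULL) {
  req <- c("county_id", "province_id", "year", "adjusted_intensity")
  miss <- setdiff(req, names(estimates))
  if (length(miss) > 0) {
    abort(paste0("`estimates` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  wide <- estimates %>%
    select(dplyr::all_of(req)) %>%
    tidyr::pivot_wider(
      names_from = "year", values_from = "adjusted_intensity",
      names_sort = TRUE
    ) %>%
    arrange(.data$province_id, .data$county_id)
  if (is.null(path)) return(wide)
  readr::write_csv(wide, path)
  invisible(wide)
}
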