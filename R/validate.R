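#' Zonal extraction: area-weighted county means of a gridded field
#'
#' Aggregates a gridded intensity field to counties through an explicit
#' cell-to-county weight lookup (the weight of a cell is the area of its
#' intersection with the county, in any consistent unit). This replaces a
#' GIS polygon-overlay step with a testable contract: the county value is
#' the weighted mean of the cells it covers. Counties with no covered cell
#' are omitted with a warning.
#'
#' @param grid A data frame with `cell_id` and `value` (one row per grid
#'   cell).
#' @param weights A data frame with `cell_id`, `county_id`, `weight`
#'   (weight > 0); a cell may contribute to several counties.
#' @return A tibble `county_id`, `value` (area-weighted mean), `n_cells`.
#' @examples
#' grid <- tibble::tibble(cell_id = 1:2, value = c(2, 4))
#' w <- tibble::tibble(cell_id = 1:2, county_id = "c1", weight = 1)
#' zonal_extract(grid, w)
#' @export
zonal_extract <- function(grid, weights) {
  if (!all(c("cell_id", "value") %in% names(grid))) {
    abort("`grid` needs columns cell_id and value")
  }
  if (!all(c("cell_id", "county_id", "weight") %in% names(weights))) {
    abort("`weights` needs columns cell_id, county_id, weight")
  }
  if (any(weights$weight <= 0)) abort("weights must be positive")

  covered <- weights %>% semi_join(grid, by = "cell_id")
  dropped <- setdiff(unique(weights$county_id), unique(covered$county_id))
  if (length(covered$county_id) == 0) {
    abort("no county intersects any grid cell")
  }
  if (length(dropped) > 0) {
    warn(paste0(length(dropped), " county(ies) cover no grid cell; omitted: ",
                paste(utils::head(dropped, 5), collapse = ", ")))
  }
  covered %>%
    inner_join(grid[c("cell_id", "value")], by = "cell_id") %>%
    group_by(.data$county_id) %>%
    summarise(
      value = sum(.data$weight * .data$value) / sum(.data$weight),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}

#' Compare county estimates against a reference product
#'
#' Pearson correlation, linear-fit R2 and mean bias between two county-level
#' intensity series over their shared counties. By default the linear fit
#' regresses the reference on the estimate (`b ~ a`); flip with
#' `direction`. Pearson r itself is symmetric.
#'
#' @param a A data frame with `county_id` and a value column (the pipeline's
#'   estimate).
#' @param b Same layout (the reference product).
#' @param value Name of the value column in both inputs (default
#'   `"value"`).
#' @param name Label for the reference product (stored in the result).
#' @param year Optional year label carried through to the result.
#' @param direction `"b_on_a"` (default) or `"a_on_b"`: which series is the
#'   response of the linear fit whose R2 is reported.
#' @return A one-row `comparison` tibble: `year`, `reference`, `n`,
#'   `pearson_r`, `r_squared`, `bias` (mean of a - b, same unit as the
#'   inputs).
#' @export
compare_estimates <- function(a, b, value = "value", name = "reference",
                              year = NA, direction = c("b_on_a", "a_on_b")) {
  direction <- match.arg(direction)
  for (d in list(a, b)) {
    if (!all(c("county_id", value) %in% names(d))) {
      abort(paste0("inputs need columns county_id and `", value, "`"))
    }
  }
  shared <- inner_join(
    a %>% select("county_id", a_val = dplyr::all_of(value)),
    b %>% select("county_id", b_val = dplyr::all_of(value)),
    by = "county_id"
  )
  if (nrow(shared) < 3) abort("fewer than 3 shared counties")
  if (sd(shared$a_val) == 0 || sd(shared$b_val) == 0) {
    abort("zero variance in one of the series; correlation undefined")
  }
  r <- cor(shared$a_val, shared$b_val)
  fit <- if (direction == "b_on_a") {
    lm(b_val ~ a_val, data = shared)
  } else {
    lm(a_val ~ b_val, data = shared)
  }
  resp <- stats::model.response(stats::model.frame(fit))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((resp - mean(resp))^2)
  out <- tibble::tibble(
    year = year,
    reference = name,
    n = nrow(shared),
    pearson_r = r,
    r_squared = r2,
    bias = mean(shared$a_val - shared$b_val)
  )
  structure(out, class = c("comparison", class(out)))
}
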