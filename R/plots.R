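#' Plot an indicator importance report
#'
#' Horizontal bars of relative importance (%), with selected indicators
#' highlighted when the report has been through [select_indicators()].
#'
#' @param object An `importance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.importance_report <- function(object, ...) {
  d <- as_tibble(object)
  d$indicator <- stats::reorder(d$indicator, d$importance_pct)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$importance_pct, y = .data$indicator
  ))
  if ("selected" %in% names(d)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$selected)) +
      ggplot2::scale_fill_manual(
        values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
        name = "selected"
      )
  } else {
    p <- p + ggplot2::geom_col(fill = "#2c7fb8")
  }
  p +
    ggplot2::labs(
      x = "Relative importance (%)", y = NULL,
      title = "Random-forest indicator importance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot downscaling model covariate importance
#'
#' @param object A `downscaler`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.downscaler <- function(object, ...) {
  d <- tidy(object)
  d$covariate <- stats::reorder(d$covariate, d$importance_pct)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$importance_pct, y = .data$covariate
  )) +
    ggplot2::geom_col(fill = "#31a354") +
    ggplot2::labs(
      x = "Importance (%)", y = NULL,
      title = "Downscaling model covariate importance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the national emission and intensity trend
#'
#' Two-panel trend of national total emissions (t CO2-eq) and mean
#' intensity (t CO2-eq / km2) over years.
#'
#' @param series Output of [national_series()].
#' @return A ggplot object (facetted).
#' @export
plot_national_series <- function(series) {
  d <- series %>%
    select("year", "total_t", "mean_intensity") %>%
    tidyr::pivot_longer(-"year", names_to = "measure") %>%
    mutate(measure = dplyr::recode(.data$measure,
      total_t = "Total emissions (t CO2-eq)",
      mean_intensity = "Mean intensity (t CO2-eq/km2)"
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Year", y = NULL,
                  title = "National crop-farming emission trend") +
    ggplot2::theme_minimal()
}

#' Scatter of county estimates against a reference product
#'
#' @param a,b Data frames with `county_id` and a value column (estimate and
#'   reference respectively).
#' @param value Value column name in both inputs.
#' @return A ggplot object with the 1:1 line and the linear fit.
#' @export
plot_county_comparison <- function(a, b, value = "value") {
  shared <- inner_join(
    a %>% select("county_id", estimate = dplyr::all_of(value)),
    b %>% select("county_id", reference = dplyr::all_of(value)),
    by = "county_id"
  )
  ggplot2::ggplot(shared, ggplot2::aes(
    x = .data$estimate, y = .data$reference
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         se = FALSE, color = "#de2d26") +
    ggplot2::labs(
      x = "Estimated intensity (t CO2-eq/km2)",
      y = "Reference intensity (t CO2-eq/km2)",
      title = "County-level comparison against reference"
    ) +
    ggplot2::theme_minimal()
}
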