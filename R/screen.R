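#' Rank candidate indicators by random-forest relative importance
#'
#' Fits a random-forest regression of emission intensity on a set of
#' candidate per-area indicators over the pooled (region, year) rows and
#' reports each indicator's relative importance rescaled to percent. The
#' default importance flavour is impurity decrease (the mainstream RF
#' default); permutation importance is available behind `importance`.
#'
#' @param data A data frame with one row per (region, year): the target
#'   column plus the candidate indicator columns, all expressed per unit
#'   land area. No missing values.
#' @param target Name of the target column (default `"intensity"`).
#' @param indicators Character vector of indicator column names; defaults to
#'   every numeric column except the target and any of `region_id`, `year`.
#' @param n_trees Number of trees (default 500).
#' @param mtry Covariates tried per split; default `max(1, floor(p / 3))`,
#'   the regression convention.
#' @param seed Integer seed; the forest (single-threaded) is fully
#'   deterministic given it.
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return An `importance_report` tibble with columns `indicator`,
#'   `importance_pct` (sums to 100) and `rank`, sorted by descending
#'   importance (ties broken by indicator name). Attributes record seed,
#'   number of trees and importance flavour.
#' @examples
#' w <- simulate_crop_world(n_provinces = 5, counties_per_province = 4,
#'                          years = 2000:2004, seed = 1)
#' rank_indicators(w$indicators, seed = 1)
#' @seealso [select_indicators()] for the cumulative-importance cut.
#' @export
rank_indicators <- function(data, target = "intensity", indicators = NULL,
                            n_trees = 500, mtry = NULL, seed = 1,
                            importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  if (!target %in% names(data)) {
    abort(paste0("target column `", target, "` not found"))
  }
  if (is.null(indicators)) {
    drop <- c(target, "region_id", "year", "area_km2")
    indicators <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], drop)
  }
  if (length(indicators) == 0) abort("no indicator columns to rank")
  miss <- setdiff(indicators, names(data))
  if (length(miss) > 0) {
    abort(paste0("indicator column(s) not found: ", paste(miss, collapse = ", ")))
  }
  m <- data[c(target, indicators)]
  if (anyNA(m)) abort("indicator matrix contains missing values")
  if (nrow(m) < 2) abort("need at least 2 rows to rank indicators")
  y <- m[[target]]
  if (length(unique(y)) < 2) {
    abort("target is constant; importance is undefined")
  }

  if (is.null(mtry)) mtry <- max(1L, floor(length(indicators) / 3))
  fit <- ranger::ranger(
    x = as.data.frame(m[indicators]), y = y,
    num.trees = n_trees, mtry = mtry,
    importance = importance, seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  # permutation importance can dip below zero for pure-noise columns;
  # clamp so the percent scale stays well defined
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) abort("all importances are zero; cannot normalize")

  out <- tibble::tibble(
    indicator = names(imp),
    importance_pct = unname(100 * imp / sum(imp))
  ) %>%
    arrange(dplyr::desc(.data$importance_pct), .data$indicator) %>%
    mutate(rank = row_number())
  structure(out,
    class = c("importance_report", class(out)),
    seed = seed, n_trees = n_trees, importance = importance
  )
}

#' Select indicators by cumulative relative importance
#'
#' Sorts indicators by descending importance and selects the shortest prefix
#' whose cumulative importance reaches the threshold. With the published
#' 12-indicator importance vector and the default threshold of 0.95 this
#' rule selects four indicators (total population, sown area of rice,
#' volume of effective component of nitrogenous fertilizer, output of grain
#' crops) with a cumulative share of 95.76%.
#'
#' @param report An importance report: a data frame with `indicator` and
#'   `importance_pct` columns summing to 100 (e.g. from
#'   [rank_indicators()]).
#' @param cum_threshold Cumulative-importance fraction in (0, 1]; default
#'   0.95.
#' @return The report tibble sorted by descending importance with added
#'   columns `cumulative_pct` and logical `selected`; attribute
#'   `cumulative_selected` holds the selected prefix's cumulative share in
#'   percent.
#' @examples
#' rep <- tibble::tibble(
#'   indicator = c("a", "b", "c"),
#'   importance_pct = c(70, 27, 3)
#' )
#' select_indicators(rep, 0.95)
#' @export
select_indicators <- function(report, cum_threshold = 0.95) {
  if (!all(c("indicator", "importance_pct") %in% names(report))) {
    abort("`report` needs columns indicator and importance_pct")
  }
  if (!is.numeric(cum_threshold) || length(cum_threshold) != 1 ||
      cum_threshold <= 0 || cum_threshold > 1) {
    abort("`cum_threshold` must be a single number in (0, 1]")
  }
  tot <- sum(report$importance_pct)
  if (abs(tot - 100) > 1e-6) {
    abort(paste0("importances must sum to 100 (got ", format(tot), ")"))
  }

  out <- report %>%
    arrange(dplyr::desc(.data$importance_pct), .data$indicator) %>%
    mutate(
      rank = row_number(),
      cumulative_pct = cumsum(.data$importance_pct)
    )
  # shortest prefix whose cumulative share reaches the threshold; the small
  # tolerance keeps exact boundary cases (e.g. equal shares) inclusive
  k <- which(out$cumulative_pct >= 100 * cum_threshold - 1e-9)[1]
  if (is.na(k)) k <- nrow(out)
  out <- mutate(out, selected = row_number() <= k)
  structure(out,
    class = unique(c("importance_report", class(out))),
    cumulative_selected = out$cumulative_pct[k],
    cum_threshold = cum_threshold,
    seed = attr(report, "seed"),
    n_trees = attr(report, "n_trees"),
    importance = attr(report, "importance")
  )
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Indicator importance report")
  if (!is.null(attr(x, "n_trees"))) {
    cat(" (", attr(x, "importance"), " importance, ",
        attr(x, "n_trees"), " trees, seed ", attr(x, "seed"), ")", sep = "")
  }
  cat("\n")
  if (!is.null(attr(x, "cumulative_selected"))) {
    cat("Selected ", sum(x$selected), " of ", nrow(x),
        " indicators; cumulative importance ",
        sprintf("%.2f%%", attr(x, "cumulative_selected")), "\n", sep = "")
  }
  NextMethod()
  invisible(x)
}
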