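#' Activity categories of the crop-farming inventory
#'
#' The six agricultural activities whose primary and secondary emissions the
#' inventory accounts for: crop residue open burning, rice cultivation,
#' cropland emissions, machinery use, nitrogen fertilizer production and
#' pesticide production. Emissions from cropland change, peat drainage or
#' burning and forest-product harvesting are deliberately out of scope.
#'
#' @return Character vector of the six activity names.
#' @export
crop_activities <- function() {
  c(
    "residue_open_burning", "rice_cultivation", "cropland_emissions",
    "machinery_use", "n_fertilizer_production", "pesticide_production"
  )
}

#' Default 100-year global warming potentials
#'
#' GWP100 multipliers used to express CH4 and N2O emissions in CO2
#' equivalents. Defaults follow the IPCC AR4 convention (CH4 = 25,
#' N2O = 298), the convention of the source-inventory era; override by
#' passing your own table to [compute_emissions()].
#'
#' @return A tibble with columns `gas` and `gwp`. GWP of CO2 is 1 by
#'   definition.
#' @examples
#' default_gwp()
#' @export
default_gwp <- function() {
  tibble::tibble(
    gas = c("CO2", "CH4", "N2O"),
    gwp = c(1, 25, 298)
  )
}

#' Illustrative default emission-factor table (synthetic)
#'
#' A unit-consistent, order-of-magnitude-plausible emission-factor table for
#' the six inventory activities. These are *illustrative placeholder values*,
#' not a published inventory's factors: real applications must supply their
#' own EF table (same columns) drawn from the inventory literature for their
#' region and period. The schema permits any (activity, gas) pairing; an
#' activity may emit several gases.
#'
#' @return A tibble with columns `activity`, `gas`, `ef` (tons of gas per
#'   activity unit) and `unit` (the unit the activity amount must be
#'   expressed in).
#' @examples
#' default_emission_factors()
#' @export
default_emission_factors <- function() {
  tibble::tribble(
    ~activity,                  ~gas,  ~ef,      ~unit,
    "residue_open_burning",     "CO2", 1.40,     "t dry residue",
    "residue_open_burning",     "CH4", 0.0027,   "t dry residue",
    "residue_open_burning",     "N2O", 0.00007,  "t dry residue",
    "rice_cultivation",         "CH4", 13.0,     "km2 sown",
    "cropland_emissions",       "N2O", 0.0157,   "t N applied",
    "machinery_use",            "CO2", 0.18,     "t diesel-equivalent",
    "n_fertilizer_production",  "CO2", 2.10,     "t N produced",
    "n_fertilizer_production",  "N2O", 0.00015,  "t N produced",
    "pesticide_production",     "CO2", 18.0,     "t active ingredient"
  )
}

# validate an EF table against the schema contract
check_ef_table <- function(efs) {
  req <- c("activity", "gas", "ef")
  miss <- setdiff(req, names(efs))
  if (length(miss) > 0) {
    abort(paste0("emission-factor table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(efs$ef < 0)) abort("emission factors must be non-negative")
  if (anyDuplicated(efs[c("activity", "gas")]) > 0) {
    abort("duplicate (activity, gas) rows in emission-factor table")
  }
  invisible(efs)
}

check_gwp_table <- function(gwps) {
  if (!all(c("gas", "gwp") %in% names(gwps))) {
    abort("GWP table needs columns `gas` and `gwp`")
  }
  if (any(gwps$gwp <= 0)) abort("GWP values must be positive")
  co2 <- gwps$gwp[gwps$gas == "CO2"]
  if (length(co2) == 1 && abs(co2 - 1) > 1e-12) {
    abort("GWP of CO2 must equal 1")
  }
  invisible(gwps)
}
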