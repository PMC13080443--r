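#' Units recognised in parameter sets
#'
#' The accounting chain works with a small closed set of units. Mass units
#' (kg, MT) interconvert by a factor of 1000; annual and daily per-capita
#' intakes interconvert by 1000/365. Count units for planting material
#' (bundles, used for cassava stems) never convert to mass: the chain only
#' ever divides a bundle quantity by a bundles-per-hectare seed rate, so no
#' mass equivalent is needed.
#'
#' @return Character vector of valid unit names.
#' @export
#' @examples
#' reach_units()
reach_units <- function() {
  c("kg", "MT", "bundles", "ha", "kg_per_ha", "bundles_per_ha", "MT_per_ha",
    "kg_per_person_year", "g_per_person_day", "persons", "households",
    "fraction", "percent")
}

# unit of the per-hectare numerator, e.g. kg_per_ha -> kg
seed_rate_numerator <- function(unit) {
  switch(unit,
    kg_per_ha = "kg",
    bundles_per_ha = "bundles",
    abort(sprintf("'%s' is not a seed-rate unit (kg_per_ha or bundles_per_ha)", unit))
  )
}

is_seed_mass_unit <- function(unit) unit %in% c("kg", "MT")

#' Convert a quantity between compatible units
#'
#' Only declared-compatible pairs convert: kg <-> MT (factor 1000) and
#' kg_per_person_year <-> g_per_person_day (factor 1000/365). Any other
#' request, in particular between mass and count (bundles) units, is an
#' error.
#'
#' @param value Numeric quantity (vectorised).
#' @param from,to Unit names from [reach_units()].
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' convert_quantity(349249350, "kg", "MT")
#' convert_quantity(259, "kg_per_person_year", "g_per_person_day")
convert_quantity <- function(value, from, to) {
  stopifnot(is.numeric(value))
  if (identical(from, to)) return(value)
  key <- paste(from, to, sep = "->")
  factor <- switch(key,
    "kg->MT" = 1 / 1000,
    "MT->kg" = 1000,
    "kg_per_person_year->g_per_person_day" = 1000 / 365,
    "g_per_person_day->kg_per_person_year" = 365 / 1000,
    abort(sprintf("no declared conversion from '%s' to '%s'", from, to),
          class = "bioreach_unit_error")
  )
  value * factor
}
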