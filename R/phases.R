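# The five-phase seed-to-consumption accounting chain.
#
# Phase functions are vectorised over rows: each takes a data frame with the
# named input columns (one row per country-crop), appends the phase's result
# columns, and returns a tibble, so a full run chains with the pipe. All
# arithmetic is carried at full double precision; rounding is applied only by
# the reporting layer.

required_cols <- function(data, cols, fn) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s(): missing required column(s): %s",
                  fn, paste(missing, collapse = ", ")),
          class = "bioreach_input_error")
  }
}

check_seed_unit <- function(unit) {
  bad <- setdiff(unique(unit), c("MT", "bundles"))
  if (length(bad) > 0) {
    abort(sprintf("seed_unit must be 'MT' or 'bundles', got: %s",
                  paste(bad, collapse = ", ")),
          class = "bioreach_unit_error")
  }
}

#' Phase 1: seed availability and farm-saved seed back-calculation
#'
#' Estimates the total quantity of biofortified seed planted in a year. The
#' total seed requirement is the area harvested (a conservative proxy for
#' area planted) times the seed rate; the excess of that requirement over
#' the commercially produced seed supply must have come from farm-saved seed
#' (FSS). The FSS-to-produced-seed ratio is assumed identical for
#' biofortified and conventional varieties, so biofortified FSS is the
#' commercial biofortified seed times that ratio.
#'
#' For crops planted from mass-measured seed (`seed_unit = "MT"`), the seed
#' rate is in kg/ha and the seed requirement is converted to MT; for crops
#' planted from counted material (`seed_unit = "bundles"`, cassava stems),
#' the rate is in bundles/ha and no conversion is applied.
#'
#' @param data Data frame with columns `bf_seed_produced` (commercial
#'   biofortified seed, MT or bundles), `area_harvested` (ha), `seed_rate`
#'   (kg/ha or bundles/ha), `total_seed_produced` (all varieties, same unit
#'   as `bf_seed_produced`), and optionally `seed_unit` ("MT", the default,
#'   or "bundles").
#' @return The input tibble with columns `total_seed_used` (seed requirement,
#'   seed unit), `fss_ratio` (farm-saved seed over seed produced, clamped at
#'   0), `bf_fss` (biofortified farm-saved seed), `total_bf_seed_used`
#'   (commercial plus farm-saved biofortified seed) and `fss_clamped`
#'   (TRUE where commercial production exceeded the requirement and the raw
#'   ratio was negative).
#' @export
#' @examples
#' tibble::tibble(
#'   bf_seed_produced = 7244, area_harvested = 11641645,
#'   seed_rate = 30, total_seed_produced = 146708
#' ) |> estimate_seed_availability()
estimate_seed_availability <- function(data) {
  required_cols(data, c("bf_seed_produced", "area_harvested", "seed_rate",
                        "total_seed_produced"), "estimate_seed_availability")
  data <- as_tibble(data)
  if (!"seed_unit" %in% names(data)) data$seed_unit <- "MT"
  check_seed_unit(data$seed_unit)
  if (any(data$total_seed_produced <= 0)) {
    abort("total_seed_produced must be strictly positive (FSS ratio undefined)",
          class = "bioreach_input_error")
  }
  if (any(data$bf_seed_produced <= 0) || any(data$area_harvested <= 0) ||
      any(data$seed_rate <= 0)) {
    abort("seed-availability inputs must be strictly positive",
          class = "bioreach_input_error")
  }
  out <- data %>%
    mutate(
      total_seed_used = .data$area_harvested * .data$seed_rate /
        if_else(.data$seed_unit == "MT", 1000, 1),
      fss_ratio_raw = (.data$total_seed_used - .data$total_seed_produced) /
        .data$total_seed_produced,
      fss_clamped = .data$fss_ratio_raw < 0,
      fss_ratio = pmax(0, .data$fss_ratio_raw),
      bf_fss = .data$bf_seed_produced * .data$fss_ratio,
      total_bf_seed_used = .data$bf_seed_produced + .data$bf_fss
    ) %>%
    select(-"fss_ratio_raw")
  if (any(out$fss_clamped)) {
    warn(paste("commercial seed production exceeds the estimated seed",
               "requirement; farm-saved seed clamped to 0"))
  }
  out
}

#' Phase 2: production of the biofortified crop
#'
#' Converts the available biofortified seed into area planted (seed over
#' seed rate), harvest (area times mean yield), and the edible supply left
#' for human consumption after deducting the harvest shares retained as
#' seed for the next season, fed to animals, and lost post-harvest.
#'
#' @param data Data frame with columns `total_bf_seed_used` (from
#'   [estimate_seed_availability()]), `seed_rate`, `yield_per_ha` (MT/ha),
#'   `fss_frac`, `feed_frac`, `phl_frac` (fractions of harvest in `[0, 1)`
#'   summing to less than 1), and optionally `seed_unit`.
#' @return Input tibble with columns `area_planted` (ha), `harvest` (MT) and
#'   `edible_supply` (MT).
#' @export
#' @examples
#' tibble::tibble(
#'   total_bf_seed_used = 380440, seed_rate = 120, yield_per_ha = 3.5,
#'   fss_frac = 0.04, feed_frac = 0.02, phl_frac = 0.04
#' ) |> estimate_production()
estimate_production <- function(data) {
  required_cols(data, c("total_bf_seed_used", "seed_rate", "yield_per_ha",
                        "fss_frac", "feed_frac", "phl_frac"),
                "estimate_production")
  data <- as_tibble(data)
  if (!"seed_unit" %in% names(data)) data$seed_unit <- "MT"
  check_seed_unit(data$seed_unit)
  fr <- data[c("fss_frac", "feed_frac", "phl_frac")]
  if (any(unlist(fr) < 0) || any(unlist(fr) >= 1)) {
    abort("deduction fractions must lie in [0, 1)",
          class = "bioreach_input_error")
  }
  if (any(rowSums(fr) >= 1)) {
    abort("deduction fractions (seed + feed + post-harvest losses) sum to >= 1",
          class = "bioreach_input_error")
  }
  data %>%
    mutate(
      area_planted = .data$total_bf_seed_used *
        if_else(.data$seed_unit == "MT", 1000, 1) / .data$seed_rate,
      harvest = .data$area_planted * .data$yield_per_ha,
      edible_supply = .data$harvest *
        (1 - .data$fss_frac - .data$feed_frac - .data$phl_frac)
    )
}

#' Rescale a survey yield by a reference year-over-year ratio
#'
#' When no monitoring survey is available for the analysis year, the most
#' recent survey yield is carried forward and rescaled by the ratio of
#' national reference yields (e.g. FAOSTAT) between the two years, so that
#' weather- and pest-related year effects are retained.
#'
#' @param base_yield Survey yield in the reference (earlier) year, MT/ha.
#' @param ref_yield_prev,ref_yield_curr National reference yields (MT/ha)
#'   for the survey year and the analysis year.
#' @return Adjusted yield in MT/ha (full precision; round at report time).
#' @export
#' @examples
#' adjust_yield(8.2, 6.0145, 6.3459)  # ~8.65
adjust_yield <- function(base_yield, ref_yield_prev, ref_yield_curr) {
  if (any(base_yield <= 0) || any(ref_yield_prev <= 0) ||
      any(ref_yield_curr <= 0)) {
    abort("yields must be strictly positive", class = "bioreach_input_error")
  }
  base_yield * ref_yield_curr / ref_yield_prev
}

#' Phase 3: on-farm consumers and on-farm consumption
#'
#' The farming population is the number of households growing the
#' biofortified crop times the mean household size; the quantity consumed
#' on-farm is that population times the annual per-capita on-farm intake.
#'
#' @param data Data frame with columns `households` (count), `household_size`
#'   (persons per household, > 0) and `intake_onfarm` (kg/person/year, > 0).
#' @return Input tibble with columns `farming_population` (persons) and
#'   `onfarm_quantity` (MT).
#' @export
#' @examples
#' tibble::tibble(households = 2552319, household_size = 2.8,
#'                intake_onfarm = 187) |> estimate_onfarm()
estimate_onfarm <- function(data) {
  required_cols(data, c("households", "household_size", "intake_onfarm"),
                "estimate_onfarm")
  data <- as_tibble(data)
  if (any(data$households < 0) || any(data$household_size <= 0) ||
      any(data$intake_onfarm <= 0)) {
    abort(paste("households must be >= 0; household_size and intake_onfarm",
                "must be > 0"), class = "bioreach_input_error")
  }
  data %>%
    mutate(
      farming_population = .data$households * .data$household_size,
      onfarm_quantity = .data$farming_population * .data$intake_onfarm / 1000
    )
}

#' Default off-farm replacement scenarios
#'
#' The full-replacement scenario assumes market consumers obtain 100% of
#' their annual intake of the crop from biofortified varieties; the
#' half-replacement scenario assumes 50%. The replacement fraction is a
#' continuous parameter, so any other scenario set can be supplied.
#'
#' @return Tibble with columns `label` and `replacement`.
#' @export
#' @examples
#' default_scenarios()
default_scenarios <- function() {
  tibble(label = c("full replacement", "half replacement"),
         replacement = c(1, 0.5))
}

#' Phase 4: off-farm quantity and off-farm consumers
#'
#' The quantity reaching the market is the edible supply minus on-farm
#' consumption (clamped at zero, with a warning, if on-farm consumption
#' exceeds supply). Under a replacement scenario, each market consumer's
#' biofortified intake is the replacement fraction times the national
#' per-capita intake, and the off-farm population is the market quantity
#' divided by that intake.
#'
#' @param data Data frame with columns `edible_supply` (MT),
#'   `onfarm_quantity` (MT) and `intake_national` (kg/person/year, > 0).
#' @param scenarios Data frame with columns `label` and `replacement`
#'   (fractions in (0, 1]); defaults to [default_scenarios()].
#' @return Tibble with one row per input row and scenario: adds `label`,
#'   `replacement`, `intake_offfarm` (kg/person/year), `offfarm_quantity`
#'   (MT), `offfarm_population` (persons) and `offfarm_clamped`.
#' @export
#' @examples
#' tibble::tibble(edible_supply = 9980420, onfarm_quantity = 2125839,
#'                intake_national = 103) |> estimate_offfarm()
estimate_offfarm <- function(data, scenarios = default_scenarios()) {
  required_cols(data, c("edible_supply", "onfarm_quantity", "intake_national"),
                "estimate_offfarm")
  required_cols(scenarios, c("label", "replacement"), "estimate_offfarm")
  if (any(scenarios$replacement <= 0) || any(scenarios$replacement > 1)) {
    abort("replacement fractions must lie in (0, 1]",
          class = "bioreach_input_error")
  }
  if (any(data$intake_national <= 0)) {
    abort("intake_national must be > 0", class = "bioreach_input_error")
  }
  data <- as_tibble(data)
  raw <- data$edible_supply - data$onfarm_quantity
  if (any(raw < 0)) {
    warn(paste("on-farm consumption exceeds edible supply;",
               "off-farm quantity clamped to 0"))
  }
  data$offfarm_quantity <- pmax(0, raw)
  data$offfarm_clamped <- raw < 0
  tidyr::crossing(data, as_tibble(scenarios)) %>%
    mutate(
      intake_offfarm = .data$replacement * .data$intake_national,
      offfarm_population = .data$offfarm_quantity * 1000 /
        .data$intake_offfarm
    )
}

#' Phase 5: national reach and coverage
#'
#' Reach is the sum of the on-farm (farming) population and the off-farm
#' (market) population; coverage is reach as a percentage of the national
#' population. A reach above the national population is reported with a
#' plausibility flag, never an error.
#'
#' @param data Data frame with columns `farming_population`,
#'   `offfarm_population` and `national_population` (> 0).
#' @return Input tibble with columns `reach` (persons), `coverage_pct`
#'   (percent) and `implausible` (TRUE where reach exceeds the national
#'   population).
#' @export
#' @examples
#' tibble::tibble(farming_population = 20639216,
#'                offfarm_population = 76258065,
#'                national_population = 247504495) |> estimate_reach_coverage()
estimate_reach_coverage <- function(data) {
  required_cols(data, c("farming_population", "offfarm_population",
                        "national_population"), "estimate_reach_coverage")
  if (any(data$national_population <= 0)) {
    abort("national_population must be > 0", class = "bioreach_input_error")
  }
  as_tibble(data) %>%
    mutate(
      reach = .data$farming_population + .data$offfarm_population,
      coverage_pct = 100 * .data$reach / .data$national_population,
      implausible = .data$reach > .data$national_population
    )
}
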