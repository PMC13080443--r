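# Auxiliary computations: the seed-ratio (full-mixing) variant of the
# off-farm estimate, the daily-intake plausibility check, and the
# overlap-adjusted multi-crop reach.

#' Off-farm reach under the seed-ratio (full-mixing) assumption
#'
#' An alternative to the replacement scenarios: assume the biofortified
#' harvest mixes completely with the conventional crop before reaching the
#' market, so every market consumer's biofortified intake is the share of
#' biofortified seed among all seed used (`total_bf_seed_used /
#' total_seed_used`) times the national per-capita intake. The off-farm
#' population is the market quantity divided by that (small) intake, which
#' tends to produce much larger reach estimates; results are screened
#' against the national population and flagged, never rejected.
#'
#' @param est A `reach_estimate` (from [estimate_reach()]) or a
#'   `reach_config` (the pipeline is run first).
#' @return One-row tibble: `seed_share`, `intake_offfarm` (kg/person/year),
#'   `offfarm_population`, `reach`, `coverage_pct`, `implausible` (TRUE when
#'   reach exceeds the national population) and `flags` (list column).
#' @export
#' @examples
#' seed_ratio_method(reach_fixture("pakistan_zinc_wheat_2023"))
seed_ratio_method <- function(est) {
  if (inherits(est, "reach_config")) est <- estimate_reach(est)
  stopifnot(inherits(est, "reach_estimate"))
  total_used <- reach_value(est, "1D")
  if (total_used <= 0) {
    abort("total seed used (1D) must be > 0", class = "bioreach_input_error")
  }
  share <- reach_value(est, "1H") / total_used
  intake <- share * param_value(est$config, "4B")
  res <- tibble(
    seed_share = share,
    intake_offfarm = intake,
    offfarm_quantity = reach_value(est, "4A"),
    farming_population = reach_value(est, "3D"),
    national_population = reach_value(est, "5B"),
    offfarm_population = .data$offfarm_quantity * 1000 / .data$intake_offfarm
  ) %>%
    estimate_reach_coverage() %>%
    mutate(flags = purrr::map(.data$implausible, function(im) {
      if (im) "reach exceeds national population (seed-ratio method)"
      else character()
    })) %>%
    select("seed_share", "intake_offfarm", "offfarm_population", "reach",
           "coverage_pct", "implausible", "flags")
  res
}

#' Daily-intake plausibility screen
#'
#' Converts an annual per-capita intake to g/person/day and flags values
#' outside a plausible range. The default band of 100-600 g/day brackets
#' staple-crop consumption in the settings where biofortified crops are
#' promoted; survey-derived intakes outside it (e.g. the 710 g/day implied
#' by a 259 kg/year response) warrant substituting a food-balance-sheet
#' value.
#'
#' @param intake_annual Annual intake, kg/person/year (vectorised, >= 0).
#' @param bounds Length-2 numeric, plausible daily range in g/person/day.
#' @return Tibble with `intake_annual`, `intake_daily_g`, `plausible`, and
#'   `flag` (NA when plausible).
#' @export
#' @examples
#' intake_plausibility(c(259, 103))
intake_plausibility <- function(intake_annual, bounds = c(100, 600)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  if (any(intake_annual < 0)) {
    abort("intake_annual must be >= 0", class = "bioreach_input_error")
  }
  daily <- convert_quantity(intake_annual, "kg_per_person_year",
                            "g_per_person_day")
  tibble(
    intake_annual = intake_annual,
    intake_daily_g = daily,
    plausible = daily >= bounds[1] & daily <= bounds[2],
    flag = dplyr::case_when(
      daily < bounds[1] ~ sprintf("daily intake %.0f g below plausible %.0f g",
                                  daily, bounds[1]),
      daily > bounds[2] ~ sprintf("daily intake %.0f g above plausible %.0f g",
                                  daily, bounds[2]),
      TRUE ~ NA_character_
    )
  )
}

#' Combined reach of several crops with a consumption overlap
#'
#' Crop-level reach figures cannot simply be summed when some individuals
#' consume more than one of the crops; the combined reach discounts the sum
#' by the assumed overlapping fraction.
#'
#' @param reaches Numeric vector of per-crop reach figures (persons),
#'   non-empty, non-negative.
#' @param overlap_fraction Fraction of individuals assumed to consume more
#'   than one crop, in `[0, 1)`.
#' @return Combined reach in persons.
#' @export
#' @examples
#' overlap_adjusted_reach(c(17.9e6, 12.5e6), 0.25)  # 22.8 million
overlap_adjusted_reach <- function(reaches, overlap_fraction) {
  if (length(reaches) == 0) {
    abort("reaches must be non-empty", class = "bioreach_input_error")
  }
  if (any(reaches < 0)) {
    abort("reaches must be non-negative", class = "bioreach_input_error")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("overlap_fraction must lie in [0, 1)",
          class = "bioreach_input_error")
  }
  sum(reaches) * (1 - overlap_fraction)
}
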