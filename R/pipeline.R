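# Full pipeline: compose the five phases for one country-crop config and
# key every intermediate by its accounting ID (1A..5C), so results mirror
# the calculation worksheet layout.

PARAM_LABELS <- c(
  "1A" = "Biofortified seed produced",
  "1B" = "Total area harvested",
  "1C" = "Seed rate",
  "1D" = "Total quantity of seed (BF & NBF) used",
  "1E" = "Total seed produced",
  "1F" = "Ratio farm-saved seed / total seed produced",
  "1G" = "Farm-saved biofortified seed used",
  "1H" = "Total biofortified seed used",
  "2A" = "Seed rate",
  "2B" = "Area planted with biofortified crop",
  "2C" = "Yield of biofortified crop",
  "2D" = "Production of the biofortified crop",
  "2E" = "Farm-saved seed share of harvest",
  "2F" = "Animal feed share of harvest",
  "2G" = "Post-harvest loss share of harvest",
  "2H" = "Biofortified crop available for human consumption",
  "3A" = "Annual per-capita on-farm intake",
  "3B" = "Farming households growing the biofortified crop",
  "3C" = "Household size of farming households",
  "3D" = "Farming population consuming the biofortified crop",
  "3E" = "On-farm consumption of the biofortified crop",
  "4A" = "Off-farm consumption of the biofortified crop",
  "4B" = "Annual per-capita off-farm intake",
  "4C" = "Population consuming off-farm",
  "5A" = "Reach",
  "5B" = "Population of the country",
  "5C" = "Coverage"
)

run_phase <- function(phase, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("%s: %s", phase, conditionMessage(e)),
          class = "bioreach_phase_error")
  })
}

#' Run the five-phase reach and coverage pipeline
#'
#' Composes seed availability, production, on-farm consumption, off-farm
#' consumption and reach/coverage for one country-crop parameter set, and
#' returns every input and calculated quantity keyed by its accounting ID
#' (scenario-dependent quantities get a per-scenario suffix: `4B.1`, `4C.1`,
#' `5A.1`, `5C.1`, ...). Values are carried at full precision; use
#' [render_reach_table()] (or [round_half_up()]) for report-style rounding.
#'
#' @param cfg A `reach_config`, or a path to a YAML/JSON config.
#' @param scenarios Optional data frame of `label`/`replacement` overriding
#'   the config's scenario list.
#' @return A `reach_estimate` object: a list with `metadata`, `parameters`
#'   (tibble `id`, `label`, `value`, `unit`), `scenarios` (one row per
#'   replacement scenario with off-farm population, reach, coverage and
#'   plausibility flags), `flags`, and the originating `config`.
#' @seealso [tidy.reach_estimate()], [glance.reach_estimate()],
#'   [autoplot.reach_estimate()], [seed_ratio_method()]
#' @export
#' @examples
#' est <- estimate_reach(reach_fixture("bangladesh_zinc_rice_2023"))
#' est$scenarios[, c("label", "reach", "coverage_pct")]
estimate_reach <- function(cfg, scenarios = NULL) {
  if (is.character(cfg)) cfg <- read_reach_config(cfg)
  stopifnot(inherits(cfg, "reach_config"))
  assert_valid_config(cfg)
  vals <- config_values(cfg)
  scen <- as_tibble(scenarios %||% cfg$scenarios)

  seed <- run_phase("phase 1 (seed availability)",
    tibble(bf_seed_produced = vals$bf_seed_produced,
           area_harvested = vals$area_harvested,
           seed_rate = vals$seed_rate,
           total_seed_produced = vals$total_seed_produced,
           seed_unit = vals$seed_unit) %>%
      estimate_seed_availability())

  prod <- run_phase("phase 2 (production)",
    seed %>%
      mutate(yield_per_ha = vals$yield_per_ha,
             fss_frac = vals$fss_frac,
             feed_frac = vals$feed_frac,
             phl_frac = vals$phl_frac) %>%
      estimate_production())

  farm <- run_phase("phase 3 (on-farm consumption)",
    prod %>%
      mutate(households = vals$households,
             household_size = vals$household_size,
             intake_onfarm = vals$intake_onfarm) %>%
      estimate_onfarm())

  offfarm <- run_phase("phase 4 (off-farm consumption)",
    farm %>%
      mutate(intake_national = vals$intake_national) %>%
      estimate_offfarm(scenarios = scen))

  full <- run_phase("phase 5 (reach and coverage)",
    offfarm %>%
      mutate(national_population = vals$national_population) %>%
      estimate_reach_coverage())

  one <- full[1, ]  # scenario-independent quantities
  seed_q_unit <- vals$seed_unit
  rate_unit <- if (seed_q_unit == "bundles") "bundles_per_ha" else "kg_per_ha"

  params <- tibble(
    id = c("1A", "1B", "1C", "1D", "1E", "1F", "1G", "1H",
           "2A", "2B", "2C", "2D", "2E", "2F", "2G", "2H",
           "3A", "3B", "3C", "3D", "3E", "4A"),
    value = c(vals$bf_seed_produced, vals$area_harvested, vals$seed_rate,
              one$total_seed_used, vals$total_seed_produced, one$fss_ratio,
              one$bf_fss, one$total_bf_seed_used,
              vals$seed_rate, one$area_planted, vals$yield_per_ha,
              one$harvest, 100 * vals$fss_frac, 100 * vals$feed_frac,
              100 * vals$phl_frac, one$edible_supply,
              vals$intake_onfarm, vals$households, vals$household_size,
              one$farming_population, one$onfarm_quantity,
              one$offfarm_quantity),
    unit = c(seed_q_unit, "ha", rate_unit, seed_q_unit, seed_q_unit,
             "fraction", seed_q_unit, seed_q_unit,
             rate_unit, "ha", "MT_per_ha", "MT", "percent", "percent",
             "percent", "MT",
             "kg_per_person_year", "households", "persons", "persons", "MT",
             "MT")
  )

  k <- seq_len(nrow(full))
  scen_params <- bind_rows(
    tibble(id = paste0("4B.", k), value = full$intake_offfarm,
           unit = "kg_per_person_year"),
    tibble(id = paste0("4C.", k), value = full$offfarm_population,
           unit = "persons"),
    tibble(id = paste0("5A.", k), value = full$reach, unit = "persons"),
    tibble(id = "5B", value = vals$national_population, unit = "persons"),
    tibble(id = paste0("5C.", k), value = full$coverage_pct,
           unit = "percent")
  )
  params <- bind_rows(params, scen_params) %>%
    mutate(label = unname(PARAM_LABELS[sub("\\..*$", "", .data$id)])) %>%
    select("id", "label", "value", "unit")

  flags <- character()
  if (one$fss_clamped) flags <- c(flags, "fss_clamped")
  if (one$offfarm_clamped) flags <- c(flags, "offfarm_clamped")

  scen_out <- full %>%
    mutate(flags = purrr::map2(.data$implausible, .data$label, function(im, lb) {
      if (im) sprintf("reach exceeds national population (%s)", lb)
      else character()
    })) %>%
    select("label", "replacement", "intake_offfarm", "offfarm_quantity",
           "offfarm_population", "reach", "coverage_pct", "implausible",
           "flags")
  flags <- c(flags, unlist(scen_out$flags))

  structure(list(metadata = cfg$metadata,
                 parameters = params,
                 scenarios = scen_out,
                 flags = flags,
                 config = cfg),
            class = "reach_estimate")
}

#' Retrieve one quantity of a reach estimate by accounting ID
#'
#' @param est A `reach_estimate`.
#' @param id Accounting ID, e.g. `"2H"` or `"5C.1"`.
#' @return Numeric scalar (full precision).
#' @export
#' @examples
#' est <- estimate_reach(reach_fixture("nigeria_vita_maize_2023"))
#' reach_value(est, "1F")
reach_value <- function(est, id) {
  i <- match(id, est$parameters$id)
  if (is.na(i)) {
    abort(sprintf("no parameter '%s' in estimate", id),
          class = "bioreach_input_error")
  }
  est$parameters$value[i]
}
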