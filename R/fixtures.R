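# Shipped worked examples and the synthetic config generator used by the
# property-based tests.

FIXTURE_NAMES <- c("bangladesh_zinc_rice_2023", "pakistan_zinc_wheat_2023",
                   "nigeria_vita_maize_2023", "nigeria_vita_cassava_2023")

#' Names of the shipped country-crop parameter sets
#' @return Character vector of fixture names for [reach_fixture()].
#' @export
reach_fixtures <- function() FIXTURE_NAMES

#' Load a shipped country-crop parameter set
#'
#' Four fully provenance-tagged parameter sets ship with the package:
#' zinc rice in Bangladesh, zinc wheat in Pakistan, and vitamin A maize and
#' cassava in Nigeria, all for 2023. They are stored as YAML under
#' `inst/extdata/fixtures` and validated on load.
#'
#' @param name One of [reach_fixtures()].
#' @return A `reach_config`.
#' @export
#' @examples
#' cfg <- reach_fixture("nigeria_vita_cassava_2023")
#' cfg$parameters[cfg$parameters$id == "1A", "unit"]  # bundles
reach_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% FIXTURE_NAMES) {
    abort(sprintf("unknown fixture '%s'; valid names: %s",
                  paste(name, collapse = ", "),
                  paste(FIXTURE_NAMES, collapse = ", ")),
          class = "bioreach_config_error")
  }
  path <- system.file("extdata", "fixtures", paste0(name, ".yaml"),
                      package = "bioreach", mustWork = TRUE)
  read_reach_config(path)
}

log_unif <- function(lo, hi) 10^runif(1, log10(lo), log10(hi))

#' Generate a random valid parameter set
#'
#' Draws a schema-valid synthetic country-crop config for property-based
#' testing. Parameter ranges bracket the four shipped fixtures by roughly
#' an order of magnitude each way; the on-farm intake and household count
#' are drawn jointly so on-farm consumption stays below the edible supply
#' (the regime all four worked examples occupy; clamped regimes are
#' exercised by dedicated unit tests). Deterministic for a given seed, and
#' leaves the caller's RNG state untouched.
#'
#' @param seed Integer seed.
#' @return A validated `reach_config`.
#' @export
#' @examples
#' cfg <- random_reach_config(42)
#' length(validate_reach_config(cfg))  # 0
random_reach_config <- function(seed) {
  withr::with_seed(seed, {
    seed_unit <- sample(c("MT", "bundles"), 1)
    area_harvested <- log_unif(5e5, 1e8)
    seed_rate <- round(log_unif(3, 300), 1)
    total_seed_used <- area_harvested * seed_rate /
      (if (seed_unit == "MT") 1000 else 1)
    total_seed_produced <- total_seed_used * runif(1, 0.1, 0.9)
    bf_seed_produced <- total_seed_produced * runif(1, 0.001, 0.5)
    yield <- round(log_unif(0.5, 20), 2)
    ded <- runif(3, 0, 0.3)
    household_size <- round(runif(1, 1.5, 12), 1)
    intake_national <- round(log_unif(6, 600), 1)
    national_population <- round(log_unif(3e6, 1e9))

    # chain forward to place on-farm consumption strictly inside the supply
    fss_ratio <- (total_seed_used - total_seed_produced) / total_seed_produced
    bf_used <- bf_seed_produced * (1 + max(0, fss_ratio))
    edible <- bf_used * (if (seed_unit == "MT") 1000 else 1) / seed_rate *
      yield * (1 - sum(ded))
    intake_onfarm <- round(log_unif(3, 300), 1)
    max_households <- 0.9 * edible * 1000 / (intake_onfarm * household_size)
    households <- max(1, round(max_households * runif(1, 0.05, 1)))

    params <- tibble(
      id = c("1A", "1B", "1C", "1E", "2C", "2E", "2F", "2G",
             "3A", "3B", "3C", "4B", "5B"),
      value = c(bf_seed_produced, area_harvested, seed_rate,
                total_seed_produced, yield, ded[1], ded[2], ded[3],
                intake_onfarm, households, household_size, intake_national,
                national_population),
      unit = c(seed_unit, "ha",
               if (seed_unit == "bundles") "bundles_per_ha" else "kg_per_ha",
               seed_unit, "MT_per_ha", "fraction", "fraction", "fraction",
               "kg_per_person_year", "households", "persons",
               "kg_per_person_year", "persons"),
      source_type = "publication",
      citation = "synthetic draw",
      source_year = 2023
    )
    reach_config(
      metadata = list(country = sprintf("Synthetica-%d", seed),
                      crop = sample(c("rice", "wheat", "maize", "cassava"), 1),
                      nutrient = sample(c("zinc", "vitamin A"), 1),
                      year = 2023),
      parameters = params
    )
  })
}
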