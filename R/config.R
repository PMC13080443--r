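# Provenance-tagged country-crop parameter sets.
#
# A reach_config bundles everything one country-crop-year needs: metadata,
# a parameter table keyed by accounting IDs (1A..5B), and the replacement
# scenarios. Each parameter carries its unit and provenance, and optionally
# a high-precision override (`value_precise`) for sources whose published
# values are rounded (e.g. whole-percent food-balance shares).

PARAM_IDS_INPUT <- c("1A", "1B", "1C", "1E", "2C", "2E", "2F", "2G",
                     "3A", "3B", "3C", "4B", "5B")

SOURCE_TYPES <- c("primary_survey", "faostat", "census", "publication",
                  "worldbank")

# allowed units per input parameter ID
unit_schema <- function() {
  list(
    "1A" = c("MT", "bundles"),
    "1B" = "ha",
    "1C" = c("kg_per_ha", "bundles_per_ha"),
    "1E" = c("MT", "bundles"),
    "2C" = "MT_per_ha",
    "2E" = c("percent", "fraction"),
    "2F" = c("percent", "fraction"),
    "2G" = c("percent", "fraction"),
    "3A" = "kg_per_person_year",
    "3B" = "households",
    "3C" = "persons",
    "4B" = "kg_per_person_year",
    "5B" = "persons"
  )
}

new_reach_config <- function(metadata, parameters, scenarios) {
  structure(list(metadata = metadata,
                 parameters = parameters,
                 scenarios = scenarios),
            class = "reach_config")
}

#' Build a country-crop parameter set
#'
#' @param metadata Named list with `country`, `crop`, `nutrient` and `year`.
#' @param parameters Data frame with columns `id`, `value`, `unit`, and
#'   optionally `value_precise` (high-precision override used in
#'   calculations; the `value` field holds the value as published),
#'   `source_type` (one of primary_survey, faostat, census, publication,
#'   worldbank), `citation` and `source_year`.
#' @param scenarios Data frame with columns `label` and `replacement`;
#'   defaults to [default_scenarios()].
#' @param validate Abort (with all violations) when the config is invalid.
#' @return A `reach_config` object.
#' @export
reach_config <- function(metadata, parameters, scenarios = default_scenarios(),
                         validate = TRUE) {
  parameters <- as_tibble(parameters)
  for (col in c("value_precise", "source_type", "citation")) {
    if (!col %in% names(parameters)) parameters[[col]] <- NA
  }
  if (!"source_year" %in% names(parameters)) parameters$source_year <- NA_real_
  parameters$value_precise <- as.numeric(parameters$value_precise)
  cfg <- new_reach_config(metadata, parameters, as_tibble(scenarios))
  if (validate) assert_valid_config(cfg)
  cfg
}

#' Read a parameter set from YAML or JSON
#'
#' The file holds `metadata`, a `parameters` map keyed by accounting ID, and
#' an optional `scenarios` list; see the shipped fixtures under
#' `system.file("extdata", "fixtures", package = "bioreach")` for the layout.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config.
#' @param validate Abort (listing every violation, not just the first) when
#'   the config does not satisfy the schema.
#' @return A `reach_config` object.
#' @export
#' @examples
#' path <- system.file("extdata", "fixtures",
#'                     "bangladesh_zinc_rice_2023.yaml", package = "bioreach")
#' cfg <- read_reach_config(path)
#' cfg$metadata$country
read_reach_config <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "bioreach_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  params <- purrr::imap(raw$parameters %||% list(), function(p, id) {
    tibble(
      id = id,
      value = as.numeric(p$value %||% NA_real_),
      value_precise = as.numeric(p$value_precise %||% NA_real_),
      unit = as.character(p$unit %||% NA_character_),
      source_type = as.character(p$source_type %||% NA_character_),
      citation = as.character(p$citation %||% NA_character_),
      source_year = as.numeric(p$year %||% NA_real_)
    )
  }) %>% bind_rows()
  scen <- if (is.null(raw$scenarios)) {
    default_scenarios()
  } else {
    purrr::map(raw$scenarios, ~ tibble(label = .x$label,
                                       replacement = as.numeric(.x$replacement))) %>%
      bind_rows()
  }
  cfg <- new_reach_config(raw$metadata %||% list(), params, scen)
  if (validate) assert_valid_config(cfg)
  cfg
}

#' Validate a parameter set against the schema
#'
#' Validation is total: any input produces a (possibly empty) character
#' vector naming every violation, with parameter-ID-specific messages; it
#' never throws.
#'
#' @param cfg A `reach_config` (or anything shaped like one).
#' @return Character vector of violations; zero-length when valid.
#' @export
#' @examples
#' cfg <- reach_fixture("pakistan_zinc_wheat_2023")
#' validate_reach_config(cfg)  # character(0)
validate_reach_config <- function(cfg) {
  v <- character()
  md <- cfg$metadata
  for (field in c("country", "crop", "nutrient", "year")) {
    if (is.null(md[[field]])) {
      v <- c(v, sprintf("metadata: missing field '%s'", field))
    }
  }
  p <- cfg$parameters
  if (is.null(p) || nrow(p) == 0) {
    return(c(v, "parameters: none supplied"))
  }
  if (anyDuplicated(p$id)) {
    v <- c(v, sprintf("parameters: duplicated id(s): %s",
                      paste(unique(p$id[duplicated(p$id)]), collapse = ", ")))
  }
  missing <- setdiff(PARAM_IDS_INPUT, p$id)
  for (id in missing) v <- c(v, sprintf("%s: missing required parameter", id))

  schema <- unit_schema()
  for (i in seq_len(nrow(p))) {
    id <- p$id[i]; val <- p$value[i]; unit <- p$unit[i]
    if (is.na(val) || !is.finite(val)) {
      v <- c(v, sprintf("%s: value is missing or non-numeric", id)); next
    }
    if (!is.na(unit) && !unit %in% reach_units()) {
      v <- c(v, sprintf("%s: unknown unit '%s'", id, unit))
    }
    if (id %in% names(schema) && !is.na(unit) && !unit %in% schema[[id]]) {
      v <- c(v, sprintf("%s: unit '%s' not allowed (expected %s)", id, unit,
                        paste(schema[[id]], collapse = " or ")))
    }
    if (id %in% c("2E", "2F", "2G")) {
      hi <- if (identical(unit, "percent")) 100 else 1
      frac <- p$value_precise[i] %|na|% val
      if (frac < 0 || frac >= hi) {
        v <- c(v, sprintf("%s: fraction out of range [0, %s)", id, hi))
      }
    } else if (id == "3B") {
      if (val < 0) v <- c(v, sprintf("%s: must be >= 0", id))
    } else if (id %in% PARAM_IDS_INPUT) {
      if (val <= 0) v <- c(v, sprintf("%s: must be strictly positive", id))
    }
    st <- p$source_type[i]
    if (is.na(st)) {
      v <- c(v, sprintf("%s: missing provenance (source_type)", id))
    } else if (!st %in% SOURCE_TYPES) {
      v <- c(v, sprintf("%s: source_type '%s' not one of %s", id, st,
                        paste(SOURCE_TYPES, collapse = ", ")))
    }
  }

  # cross-parameter unit consistency for the seed block
  u <- function(id) p$unit[match(id, p$id)]
  if (all(c("1A", "1E", "1C") %in% p$id)) {
    if (!is.na(u("1A")) && !is.na(u("1E")) && u("1A") != u("1E")) {
      v <- c(v, sprintf("1A/1E: seed units differ ('%s' vs '%s')",
                        u("1A"), u("1E")))
    }
    rate_u <- u("1C")
    if (!is.na(rate_u) && rate_u %in% c("kg_per_ha", "bundles_per_ha")) {
      want <- if (rate_u == "bundles_per_ha") "bundles" else "MT"
      if (!is.na(u("1A")) && u("1A") %in% c("MT", "bundles") &&
          u("1A") != want) {
        v <- c(v, sprintf(
          "1C: seed-rate unit '%s' incompatible with seed unit '%s'",
          rate_u, u("1A")))
      }
    }
  }

  # deduction fractions must leave something edible
  if (all(c("2E", "2F", "2G") %in% p$id) &&
      !any(grepl("^2[EFG]:", v))) {
    total <- sum(purrr::map_dbl(c("2E", "2F", "2G"), function(id) {
      param_fraction(cfg, id)
    }))
    if (is.finite(total) && total >= 1) {
      v <- c(v, sprintf(
        "2E+2F+2G: deductions sum to %.3f, must be < 1", total))
    }
  }

  s <- cfg$scenarios
  if (is.null(s) || nrow(s) == 0) {
    v <- c(v, "scenarios: none supplied")
  } else {
    bad <- s$replacement <= 0 | s$replacement > 1
    if (any(bad)) {
      v <- c(v, sprintf("scenarios: replacement fraction out of (0, 1]: %s",
                        paste(s$label[bad], collapse = ", ")))
    }
    if (anyDuplicated(s$label)) v <- c(v, "scenarios: duplicated labels")
  }
  v
}

assert_valid_config <- function(cfg) {
  v <- validate_reach_config(cfg)
  if (length(v) > 0) {
    abort(paste0("invalid reach config (", length(v), " violation(s)):\n",
                 paste0("  - ", v, collapse = "\n")),
          class = "bioreach_config_error")
  }
  invisible(cfg)
}

`%|na|%` <- function(x, y) if (length(x) == 1 && is.na(x)) y else x

#' Working value of a config parameter
#'
#' Returns the value used in calculations: the high-precision override when
#' present, the published value otherwise.
#'
#' @param cfg A `reach_config`.
#' @param id Parameter ID (e.g. `"2C"`).
#' @return Numeric scalar (NA if the parameter is absent).
#' @export
param_value <- function(cfg, id) {
  i <- match(id, cfg$parameters$id)
  if (is.na(i)) return(NA_real_)
  cfg$parameters$value_precise[i] %|na|% cfg$parameters$value[i]
}

# deduction share as a fraction regardless of declared unit
param_fraction <- function(cfg, id) {
  i <- match(id, cfg$parameters$id)
  if (is.na(i)) return(NA_real_)
  val <- param_value(cfg, id)
  if (identical(cfg$parameters$unit[i], "percent")) val / 100 else val
}

# engine-facing named list of working values
config_values <- function(cfg) {
  seed_unit <- cfg$parameters$unit[match("1A", cfg$parameters$id)]
  list(
    bf_seed_produced = param_value(cfg, "1A"),
    area_harvested = param_value(cfg, "1B"),
    seed_rate = param_value(cfg, "1C"),
    total_seed_produced = param_value(cfg, "1E"),
    seed_unit = if (identical(seed_unit, "bundles")) "bundles" else "MT",
    yield_per_ha = param_value(cfg, "2C"),
    fss_frac = param_fraction(cfg, "2E"),
    feed_frac = param_fraction(cfg, "2F"),
    phl_frac = param_fraction(cfg, "2G"),
    intake_onfarm = param_value(cfg, "3A"),
    households = param_value(cfg, "3B"),
    household_size = param_value(cfg, "3C"),
    intake_national = param_value(cfg, "4B"),
    national_population = param_value(cfg, "5B")
  )
}

#' Perturb one parameter of a config
#'
#' Scales a parameter's published value and (if present) its high-precision
#' override by `1 + delta_pct/100`; used by the one-at-a-time sensitivity
#' analysis.
#'
#' @param cfg A `reach_config`.
#' @param id Parameter ID to perturb.
#' @param delta_pct Percent change (e.g. `10` for +10%).
#' @return A new `reach_config` (unvalidated; validate before running).
#' @export
perturb_config <- function(cfg, id, delta_pct) {
  i <- match(id, cfg$parameters$id)
  if (is.na(i)) {
    abort(sprintf("unknown parameter id '%s'", id),
          class = "bioreach_config_error")
  }
  f <- 1 + delta_pct / 100
  cfg$parameters$value[i] <- cfg$parameters$value[i] * f
  if (!is.na(cfg$parameters$value_precise[i])) {
    cfg$parameters$value_precise[i] <- cfg$parameters$value_precise[i] * f
  }
  cfg
}

#' @export
print.reach_config <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<reach_config> %s %s (%s), %s\n",
              md$country %||% "?", md$crop %||% "?",
              md$nutrient %||% "?", md$year %||% "?"))
  cat(sprintf("  %d parameters, %d scenario(s): %s\n",
              nrow(x$parameters), nrow(x$scenarios),
              paste(x$scenarios$label, collapse = ", ")))
  invisible(x)
}
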