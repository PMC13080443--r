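# Report-layer rendering: worksheet-style tables across country-crops,
# one-at-a-time sensitivity, and result file output. This is the only layer
# that rounds: counts, tonnages and percents to integers, ratios, yields
# and household sizes to one decimal, always half-up.

# report-time decimal places by (base) accounting ID
digits_for_id <- function(id) {
  base <- sub("\\..*$", "", id)
  ifelse(base %in% c("1F", "2C", "3C"), 1, 0)
}

id_sort_key <- function(id) {
  base <- sub("\\..*$", "", id)
  suffix <- as.integer(ifelse(grepl("\\.", id), sub("^.*\\.", "", id), "0"))
  order(substr(base, 1, 1), substr(base, 2, 2), suffix)
}

#' Render a worksheet-style comparison table
#'
#' Lays out one or more reach estimates side by side, one row per
#' accounting ID in worksheet order, with report rounding applied (values
#' become formatted strings). With no estimates, returns the header-only
#' skeleton.
#'
#' @param ... `reach_estimate` objects (or a single list of them).
#' @return Tibble with columns `id`, `indicator`, and one column per
#'   estimate named "Country crop".
#' @export
#' @examples
#' ests <- lapply(reach_fixtures(), function(n) estimate_reach(reach_fixture(n)))
#' render_reach_table(ests)
render_reach_table <- function(...) {
  ests <- list(...)
  if (length(ests) == 1 && !inherits(ests[[1]], "reach_estimate")) {
    ests <- ests[[1]]
  }
  if (length(ests) == 0) {
    return(tibble(id = character(), indicator = character()))
  }
  stopifnot(all(purrr::map_lgl(ests, inherits, "reach_estimate")))
  cols <- purrr::map(ests, function(est) {
    nm <- paste(est$metadata$country %||% "?", est$metadata$crop %||% "?")
    est$parameters %>%
      mutate(!!nm := fmt_num(.data$value, digits_for_id(.data$id))) %>%
      select("id", "label", all_of(nm))
  })
  out <- purrr::reduce(cols, dplyr::full_join, by = c("id", "label"))
  out <- out[id_sort_key(out$id), ] %>% rename(indicator = "label")
  out
}

#' One-at-a-time sensitivity of reach and coverage
#'
#' Re-runs the pipeline with one parameter perturbed by a given percentage
#' and reports, per scenario and output quantity, the baseline and
#' perturbed values and the elasticity (percent change in output per
#' percent change in input). A perturbation that makes the config invalid
#' is reported as a violation row, never an error.
#'
#' @param cfg A `reach_config`.
#' @param id Input parameter ID to perturb (e.g. `"3C"`).
#' @param delta_pct Percent perturbation (default +10).
#' @return Tibble with columns `param`, `delta_pct`, `scenario`, `quantity`
#'   (farming_population, offfarm_population, reach, coverage_pct),
#'   `baseline`, `perturbed`, `elasticity`; or, for an invalid
#'   perturbation, a one-row tibble with a `violation` column.
#' @export
#' @examples
#' sensitivity_reach(reach_fixture("bangladesh_zinc_rice_2023"), "3C", 10)
sensitivity_reach <- function(cfg, id, delta_pct = 10) {
  stopifnot(inherits(cfg, "reach_config"))
  base <- estimate_reach(cfg)
  pert_cfg <- perturb_config(cfg, id, delta_pct)
  v <- validate_reach_config(pert_cfg)
  if (length(v) > 0) {
    return(tibble(param = id, delta_pct = delta_pct,
                  violation = paste(v, collapse = "; ")))
  }
  pert <- estimate_reach(pert_cfg)
  grab <- function(est) {
    est$scenarios %>%
      mutate(farming_population = reach_value(est, "3D")) %>%
      select(scenario = "label", "farming_population",
             "offfarm_population", "reach", "coverage_pct") %>%
      pivot_longer(-"scenario", names_to = "quantity", values_to = "value")
  }
  left_join(grab(base), grab(pert) %>% rename(perturbed = "value"),
            by = c("scenario", "quantity")) %>%
    rename(baseline = "value") %>%
    mutate(param = id, delta_pct = delta_pct,
           elasticity = if_else(.data$baseline == 0, 0,
                                (.data$perturbed - .data$baseline) /
                                  .data$baseline / (delta_pct / 100))) %>%
    select("param", "delta_pct", "scenario", "quantity", "baseline",
           "perturbed", "elasticity")
}

#' Write a reach estimate to disk
#'
#' JSON output stores every value at full precision (reading it back
#' recovers the numbers bit-exactly); CSV output holds one row per
#' accounting ID with metadata columns.
#'
#' @param est A `reach_estimate`.
#' @param path Output file path.
#' @param format `"json"` or `"csv"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_reach_results <- function(est, path, format = NULL) {
  stopifnot(inherits(est, "reach_estimate"))
  format <- format %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json")
  if (format == "json") {
    payload <- list(
      metadata = est$metadata,
      parameters = est$parameters,
      scenarios = est$scenarios %>%
        mutate(flags = purrr::map_chr(.data$flags, paste, collapse = "; ")),
      flags = est$flags
    )
    # I(17) significant digits: doubles survive the write/read round trip
    # bit-exactly
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  } else if (format == "csv") {
    est$parameters %>%
      mutate(country = est$metadata$country %||% NA_character_,
             crop = est$metadata$crop %||% NA_character_,
             year = est$metadata$year %||% NA_real_,
             .before = 1) %>%
      write.csv(path, row.names = FALSE)
  } else {
    abort(sprintf("unknown format '%s'", format),
          class = "bioreach_config_error")
  }
  invisible(path)
}

#' Read back a JSON result document
#'
#' @param path Path written by [write_reach_results()] (JSON format).
#' @return List with `metadata`, `parameters` (tibble), `scenarios`
#'   (tibble) and `flags`.
#' @export
read_reach_results <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(metadata = raw$metadata,
       parameters = as_tibble(raw$parameters),
       scenarios = as_tibble(raw$scenarios),
       flags = raw$flags %||% character())
}
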