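# S3 methods for reach_estimate: print, broom-style tidy()/glance(), and a
# ggplot2 autoplot.

#' @export
print.reach_estimate <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<reach_estimate> %s %s (%s), %s\n",
              md$country %||% "?", md$crop %||% "?", md$nutrient %||% "?",
              md$year %||% "?"))
  cat(sprintf("  farming population: %s\n",
              fmt_num(reach_value(x, "3D"))))
  for (i in seq_len(nrow(x$scenarios))) {
    s <- x$scenarios[i, ]
    cat(sprintf("  %-18s reach %s (coverage %s%%)\n",
                paste0(s$label, ":"), fmt_num(s$reach),
                fmt_num(s$coverage_pct)))
  }
  if (length(x$flags) > 0) {
    cat(sprintf("  flags: %s\n", fmt_flags(x$flags)))
  }
  invisible(x)
}

#' Tidy a reach estimate into one row per accounting ID
#'
#' @param x A `reach_estimate`.
#' @param ... Unused.
#' @return Tibble with `id`, `label`, `value` (full precision) and `unit`.
#' @export
tidy.reach_estimate <- function(x, ...) {
  x$parameters
}

#' One-row summary of a reach estimate
#'
#' @param x A `reach_estimate`.
#' @param ... Unused.
#' @return One-row tibble: metadata, the reach and coverage range across
#'   scenarios, and the number of plausibility flags raised.
#' @export
glance.reach_estimate <- function(x, ...) {
  tibble(
    country = x$metadata$country %||% NA_character_,
    crop = x$metadata$crop %||% NA_character_,
    nutrient = x$metadata$nutrient %||% NA_character_,
    year = x$metadata$year %||% NA_real_,
    n_scenarios = nrow(x$scenarios),
    farming_population = reach_value(x, "3D"),
    reach_min = min(x$scenarios$reach),
    reach_max = max(x$scenarios$reach),
    coverage_min_pct = min(x$scenarios$coverage_pct),
    coverage_max_pct = max(x$scenarios$coverage_pct),
    n_flags = length(x$flags)
  )
}

#' Plot on-farm and off-farm reach by scenario
#'
#' @param object A `reach_estimate`.
#' @param ... Unused.
#' @return A ggplot: stacked on-farm/off-farm reach per replacement
#'   scenario, with the national population as a reference line.
#' @export
autoplot.reach_estimate <- function(object, ...) {
  dat <- object$scenarios %>%
    mutate(`on-farm` = reach_value(object, "3D"),
           `off-farm` = .data$offfarm_population) %>%
    select("label", "on-farm", "off-farm") %>%
    pivot_longer(-"label", names_to = "segment", values_to = "persons")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$persons,
                                    fill = .data$segment)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = reach_value(object, "5B"),
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(x) x / 1e6) +
    ggplot2::labs(
      x = NULL, y = "reach (million persons)", fill = NULL,
      title = sprintf("Reach of biofortified %s, %s %s",
                      object$metadata$crop %||% "crop",
                      object$metadata$country %||% "",
                      object$metadata$year %||% ""),
      subtitle = "dashed line: national population"
    ) +
    ggplot2::theme_minimal()
}
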