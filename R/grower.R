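# Growing-household model: turn seed-channel sales records into households
# acquiring seed per year, then project the stock of growing households
# forward under farmer-to-farmer diffusion and attrition. Used to produce
# parameter 3B when it is not supplied directly.

SEED_CHANNELS <- c("agro_dealer", "community_multiplier",
                   "public_distribution", "farmer_to_farmer")

#' Households acquiring biofortified seed per year
#'
#' One purchase is one household: where per-pack-size sales counts are
#' available (agro-dealer networks), each pack sold counts as one acquiring
#' household; where only a bulk quantity is known (e.g. public distribution
#' registers), the quantity is divided by a configured typical purchase
#' size.
#'
#' @param records Data frame of seed-channel records with columns `year`,
#'   `channel` (one of agro_dealer, community_multiplier,
#'   public_distribution, farmer_to_farmer), `quantity` (kg or bundles
#'   distributed), and optionally `pack_size` and `packs` (one row per
#'   pack-size category; `NA` where only the bulk quantity is known).
#' @param typical_purchase Typical quantity one household acquires, same
#'   unit as `quantity`; required for rows without pack counts.
#' @param tolerance Allowed relative excess of `pack_size * packs` over the
#'   recorded channel quantity (default 1%).
#' @return Tibble with `year` and `households_acquiring`.
#' @export
#' @examples
#' records <- tibble::tibble(
#'   year = 2023, channel = "agro_dealer",
#'   quantity = c(100, 400, 1000), pack_size = c(1, 4, 10),
#'   packs = c(100, 100, 100)
#' )
#' households_from_packs(records)
households_from_packs <- function(records, typical_purchase = NULL,
                                  tolerance = 0.01) {
  required_cols(records, c("year", "channel", "quantity"),
                "households_from_packs")
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    warn("no seed-channel records; 0 acquiring households")
    return(tibble(year = integer(), households_acquiring = numeric()))
  }
  bad <- setdiff(unique(records$channel), SEED_CHANNELS)
  if (length(bad) > 0) {
    abort(sprintf("unknown seed channel(s): %s (expected %s)",
                  paste(bad, collapse = ", "),
                  paste(SEED_CHANNELS, collapse = ", ")),
          class = "bioreach_input_error")
  }
  if (!"packs" %in% names(records)) records$packs <- NA_real_
  if (!"pack_size" %in% names(records)) records$pack_size <- NA_real_
  no_packs <- is.na(records$packs)
  if (any(no_packs) && is.null(typical_purchase)) {
    abort(paste("records without pack counts need a typical_purchase size",
                "to convert quantity into households"),
          class = "bioreach_config_error")
  }
  # pack-count consistency: multiplied-out packs must not exceed the
  # recorded quantity beyond tolerance
  with_packs <- records %>% filter(!is.na(.data$packs), !is.na(.data$pack_size))
  if (nrow(with_packs) > 0) {
    chk <- with_packs %>%
      group_by(.data$year, .data$channel) %>%
      summarise(sold = sum(.data$pack_size * .data$packs),
                qty = sum(.data$quantity), .groups = "drop") %>%
      filter(.data$sold > .data$qty * (1 + tolerance))
    if (nrow(chk) > 0) {
      abort(sprintf(
        "pack counts exceed recorded quantity for %s",
        paste(sprintf("%s/%s", chk$year, chk$channel), collapse = ", ")),
        class = "bioreach_input_error")
    }
  }
  records %>%
    mutate(households = if_else(is.na(.data$packs),
                                .data$quantity / (typical_purchase %||% NA_real_),
                                .data$packs)) %>%
    group_by(year = .data$year) %>%
    summarise(households_acquiring = sum(.data$households), .groups = "drop") %>%
    arrange(.data$year)
}

#' Project growing households under diffusion and attrition
#'
#' Year-on-year recursion for the stock of households growing the
#' biofortified crop: last year's growers first spread the variety
#' farmer-to-farmer (rate `diffusion`), a fraction `attrition` then stops
#' growing it, and the year's new seed acquirers are added:
#' `H_t = H_{t-1} * (1 + diffusion) * (1 - attrition) + A_t`,
#' starting from the first year's acquirers. With no diffusion and no
#' attrition the series is the cumulative sum of acquirers; with full
#' attrition it is the acquirers themselves.
#'
#' @param acquirers Data frame with columns `year` and
#'   `households_acquiring` (one row per consecutive modelled year), e.g.
#'   from [households_from_packs()].
#' @param diffusion Farmer-to-farmer diffusion rate per year, >= 0.
#' @param attrition Fraction of growers stopping per year, in `[0, 1]`.
#' @return A `grower_series` tibble with `year`, `households_acquiring` and
#'   `households` (the stock usable as parameter 3B).
#' @export
#' @examples
#' acq <- tibble::tibble(year = 2021:2023,
#'                       households_acquiring = c(1000, 1500, 2000))
#' project_growers(acq, diffusion = 0.1, attrition = 0.05)
project_growers <- function(acquirers, diffusion = 0, attrition = 0) {
  required_cols(acquirers, c("year", "households_acquiring"),
                "project_growers")
  if (diffusion < 0) {
    abort("diffusion must be >= 0", class = "bioreach_input_error")
  }
  if (attrition < 0 || attrition > 1) {
    abort("attrition must lie in [0, 1]", class = "bioreach_input_error")
  }
  acq <- as_tibble(acquirers) %>% arrange(.data$year)
  if (any(acq$households_acquiring < 0)) {
    abort("households_acquiring must be >= 0", class = "bioreach_input_error")
  }
  h <- numeric(nrow(acq))
  carry <- (1 + diffusion) * (1 - attrition)
  for (t in seq_len(nrow(acq))) {
    h[t] <- if (t == 1) acq$households_acquiring[1]
            else h[t - 1] * carry + acq$households_acquiring[t]
  }
  out <- acq %>% mutate(households = h)
  class(out) <- c("grower_series", class(out))
  attr(out, "diffusion") <- diffusion
  attr(out, "attrition") <- attrition
  out
}

#' Plot a projected grower series
#'
#' @param object A `grower_series` from [project_growers()].
#' @param ... Unused.
#' @return A ggplot: stock of growing households and new acquirers by year.
#' @export
autoplot.grower_series <- function(object, ...) {
  long <- tibble::as_tibble(object) %>%
    pivot_longer(c("households", "households_acquiring"),
                 names_to = "series", values_to = "n") %>%
    mutate(series = if_else(.data$series == "households",
                            "growing (stock)", "acquiring (new)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$n,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "year", y = "households", colour = NULL,
                  title = "Households growing the biofortified crop",
                  subtitle = sprintf("diffusion %.2f, attrition %.2f",
                                     attr(object, "diffusion"),
                                     attr(object, "attrition"))) +
    ggplot2::theme_minimal()
}
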