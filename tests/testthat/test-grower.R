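test_that("one pack sold is one acquiring household; bulk quantities divide", {
  records <- tibble::tibble(
    year = 2023, channel = "agro_dealer",
    quantity = c(100, 400, 1000), pack_size = c(1, 4, 10),
    packs = c(100, 100, 100))
  out <- households_from_packs(records)
  expect_equal(out$households_acquiring, 300)

  bulk <- tibble::tibble(year = 2023, channel = "public_distribution",
                         quantity = 600)
  expect_equal(households_from_packs(bulk, typical_purchase = 2)$households_acquiring,
               300)
  expect_error(households_from_packs(bulk), "typical_purchase",
               class = "bioreach_config_error")
})

test_that("empty records give zero households with a warning", {
  empty <- tibble::tibble(year = integer(), channel = character(),
                          quantity = numeric())
  expect_warning(out <- households_from_packs(empty), "0 acquiring")
  expect_equal(nrow(out), 0)
})

test_that("pack counts that outrun the recorded quantity are rejected", {
  bad <- tibble::tibble(year = 2023, channel = "agro_dealer",
                        quantity = 100, pack_size = 2, packs = 100)
  expect_error(households_from_packs(bad), "exceed")
  # within the 1% tolerance passes
  ok <- tibble::tibble(year = 2023, channel = "agro_dealer",
                       quantity = 199, pack_size = 2, packs = 100)
  expect_silent(households_from_packs(ok))
})

test_that("grower projection follows the diffusion-then-attrition recursion", {
  acq <- function(...) {
    v <- c(...)
    tibble::tibble(year = seq_along(v) + 2020, households_acquiring = v)
  }
  # no diffusion, no attrition: cumulative sum
  expect_equal(project_growers(acq(100, 50))$households, c(100, 150))
  expect_equal(project_growers(acq(10, 20, 30))$households, cumsum(c(10, 20, 30)))
  # diffusion only
  expect_equal(project_growers(acq(100, 0), diffusion = 0.1)$households,
               c(100, 110))
  # full attrition: only the year's acquirers remain
  expect_equal(project_growers(acq(100, 40, 7), attrition = 1)$households,
               c(100, 40, 7))
  # hand-computed mixed case
  expect_equal(project_growers(acq(100, 50), diffusion = 0.2,
                               attrition = 0.25)$households,
               c(100, 100 * 1.2 * 0.75 + 50))
})

test_that("projection is monotone in diffusion and anti-monotone in attrition", {
  acq <- tibble::tibble(year = 2019:2023,
                        households_acquiring = c(500, 800, 200, 1000, 300))
  last_h <- function(d, a) utils::tail(project_growers(acq, d, a)$households, 1)
  expect_gt(last_h(0.3, 0.1), last_h(0.1, 0.1))
  expect_lt(last_h(0.1, 0.4), last_h(0.1, 0.1))
  expect_error(project_growers(acq, diffusion = -0.1), ">= 0")
  expect_error(project_growers(acq, attrition = 1.2), "\\[0, 1\\]")
})

test_that("a projected series can supply the farming-household parameter", {
  cfg <- reach_fixture("nigeria_vita_maize_2023")
  series <- project_growers(
    tibble::tibble(year = 2021:2023,
                   households_acquiring = c(9e5, 6e5, 5e5)),
    diffusion = 0.08, attrition = 0.05)
  cfg$parameters$value[match("3B", cfg$parameters$id)] <-
    series$households[series$year == 2023]
  est <- estimate_reach(cfg)
  expect_equal(reach_value(est, "3B"), utils::tail(series$households, 1))
})
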