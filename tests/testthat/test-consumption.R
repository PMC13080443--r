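test_that("farming population and on-farm tonnage follow households and intake", {
  bd <- tibble::tibble(households = 2552319, household_size = 2.8,
                       intake_onfarm = 187) |>
    estimate_onfarm()
  expect_identical(round_half_up(bd$farming_population), 7146493)

  cs <- tibble::tibble(households = 12525666 / 5.6, household_size = 5.6,
                       intake_onfarm = 89) |>
    estimate_onfarm()
  expect_chained_cell(cs$onfarm_quantity, 1114784)

  z <- tibble::tibble(households = 0, household_size = 4, intake_onfarm = 50) |>
    estimate_onfarm()
  expect_equal(z$farming_population, 0)
  expect_equal(z$onfarm_quantity, 0)
})

test_that("off-farm quantity is the market residual and scales with intake", {
  pk <- tibble::tibble(edible_supply = 9980420, onfarm_quantity = 2125839,
                       intake_national = 103) |>
    estimate_offfarm()
  expect_equal(unique(pk$offfarm_quantity), 7854581)

  # market residual of zero supports nobody off-farm
  none <- tibble::tibble(edible_supply = 500, onfarm_quantity = 500,
                         intake_national = 100) |>
    estimate_offfarm()
  expect_true(all(none$offfarm_population == 0))

  # 1,000 MT at 50 kg/y and half replacement feeds 40,000 people
  x <- tibble::tibble(edible_supply = 1000, onfarm_quantity = 0,
                      intake_national = 50) |>
    estimate_offfarm(scenarios = data.frame(label = "half", replacement = 0.5))
  expect_equal(x$offfarm_population, 40000)
})

test_that("on-farm consumption above supply clamps the market quantity with a warning", {
  inp <- tibble::tibble(edible_supply = 100, onfarm_quantity = 150,
                        intake_national = 50)
  expect_warning(out <- estimate_offfarm(inp), "clamped")
  expect_true(all(out$offfarm_clamped))
  expect_true(all(out$offfarm_quantity == 0))
})

test_that("reach sums the two populations and coverage is screened, not rejected", {
  x <- tibble::tibble(farming_population = 20639216,
                      offfarm_population = 76258065,
                      national_population = 247504495) |>
    estimate_reach_coverage()
  expect_equal(x$reach, 96897281)
  expect_equal(round_half_up(x$coverage_pct), 39)
  expect_false(x$implausible)

  # off-farm population of zero: reach is the farming population
  y <- tibble::tibble(farming_population = 1e6, offfarm_population = 0,
                      national_population = 5e6) |>
    estimate_reach_coverage()
  expect_equal(y$reach, 1e6)

  # implausible totals flag rather than error
  z <- tibble::tibble(farming_population = 4e6, offfarm_population = 3e6,
                      national_population = 5e6) |>
    estimate_reach_coverage()
  expect_true(z$implausible)
  expect_gt(z$coverage_pct, 100)
})

test_that("replacement fractions outside (0, 1] are rejected", {
  inp <- tibble::tibble(edible_supply = 100, onfarm_quantity = 10,
                        intake_national = 50)
  expect_error(estimate_offfarm(inp, scenarios = data.frame(label = "x",
                                                            replacement = 0)),
               "replacement")
  expect_error(estimate_offfarm(inp, scenarios = data.frame(label = "x",
                                                            replacement = 1.5)),
               "replacement")
})
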