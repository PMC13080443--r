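test_that("seed requirement and farm-saved seed back-calculation match the worksheets", {
  # Bangladesh rice: area x rate, kg converted to MT
  bd <- tibble::tibble(bf_seed_produced = 7244, area_harvested = 11641645,
                       seed_rate = 30, total_seed_produced = 146708) |>
    estimate_seed_availability()
  expect_identical(round_half_up(bd$total_seed_used), 349249)

  # Nigeria maize: ratio and total biofortified seed
  ng <- tibble::tibble(bf_seed_produced = 13282, area_harvested = 5700000,
                       seed_rate = 20, total_seed_produced = 60000) |>
    estimate_seed_availability()
  expect_equal(ng$total_seed_used, 114000)
  expect_equal(ng$fss_ratio, 0.9)
  expect_identical(round_half_up(ng$total_bf_seed_used), 25236)
  expect_false(ng$fss_clamped)

  # bundles never convert to mass
  cs <- tibble::tibble(bf_seed_produced = 4845831, area_harvested = 9878773,
                       seed_rate = 60, total_seed_produced = 79820000,
                       seed_unit = "bundles") |>
    estimate_seed_availability()
  expect_equal(cs$total_seed_used, 9878773 * 60)
})

test_that("no farm-saved seed when production covers the requirement exactly", {
  x <- tibble::tibble(bf_seed_produced = 500, area_harvested = 1000,
                      seed_rate = 100, total_seed_produced = 100) |>
    estimate_seed_availability()
  expect_equal(x$fss_ratio, 0)
  expect_equal(x$total_bf_seed_used, x$bf_seed_produced)
  expect_false(x$fss_clamped)
})

test_that("excess commercial production clamps the ratio to zero with a warning", {
  inp <- tibble::tibble(bf_seed_produced = 500, area_harvested = 1000,
                        seed_rate = 100, total_seed_produced = 200)
  expect_warning(out <- estimate_seed_availability(inp), "clamped")
  expect_true(out$fss_clamped)
  expect_equal(out$fss_ratio, 0)
  expect_equal(out$total_bf_seed_used, 500)
})

test_that("degenerate seed inputs are rejected", {
  base <- tibble::tibble(bf_seed_produced = 10, area_harvested = 100,
                         seed_rate = 50, total_seed_produced = 5)
  expect_error(estimate_seed_availability(dplyr::mutate(base, total_seed_produced = 0)),
               "ratio undefined")
  expect_error(estimate_seed_availability(dplyr::mutate(base, seed_unit = "kg")),
               "seed_unit")
  expect_error(estimate_seed_availability(base[, -1]), "bf_seed_produced")
})
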