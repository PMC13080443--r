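test_that("area planted, harvest and edible supply follow seed and yield", {
  # Pakistan wheat: seed back to area at 120 kg/ha
  pk <- tibble::tibble(total_bf_seed_used = 380440, seed_rate = 120,
                       yield_per_ha = 3.5, fss_frac = 0.04, feed_frac = 0.02,
                       phl_frac = 0.04) |>
    estimate_production()
  expect_chained_cell(pk$area_planted, 3170332)

  # Nigeria maize: harvest from printed area and yield
  ng <- tibble::tibble(total_bf_seed_used = 25235.8, seed_rate = 20,
                       yield_per_ha = 1.5, fss_frac = 0.01, feed_frac = 0.39,
                       phl_frac = 0.05) |>
    estimate_production()
  expect_equal(ng$area_planted, 1261790)
  expect_chained_cell(ng$harvest, 1892685)

  # bundles divide by a per-hectare bundle rate without mass conversion
  cs <- tibble::tibble(total_bf_seed_used = 35984113, seed_rate = 60,
                       yield_per_ha = 8.65, fss_frac = 0, feed_frac = 0.3,
                       phl_frac = 0.08, seed_unit = "bundles") |>
    estimate_production()
  expect_equal(cs$area_planted, 35984113 / 60)
})

test_that("zero deductions leave the whole harvest edible", {
  x <- tibble::tibble(total_bf_seed_used = 1000, seed_rate = 100,
                      yield_per_ha = 2, fss_frac = 0, feed_frac = 0,
                      phl_frac = 0) |>
    estimate_production()
  expect_equal(x$edible_supply, x$harvest)
})

test_that("deductions must leave something edible", {
  x <- tibble::tibble(total_bf_seed_used = 1000, seed_rate = 100,
                      yield_per_ha = 2, fss_frac = 0.5, feed_frac = 0.4,
                      phl_frac = 0.2)
  expect_error(estimate_production(x), "sum to >= 1")
  expect_error(estimate_production(dplyr::mutate(x, fss_frac = -0.1)),
               "\\[0, 1\\)")
})

test_that("reference-year yield rescaling is a plain ratio", {
  expect_equal(round_half_up(adjust_yield(8.2, 6.0145, 6.3459), 2), 8.65)
  expect_equal(adjust_yield(4.2, 5, 5), 4.2)
  expect_equal(adjust_yield(10, 5, 6), 12)
  expect_error(adjust_yield(10, 0, 6), "positive")
})
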