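test_that("the comparison table lays out all country-crops in worksheet order", {
  tab <- render_reach_table(fixture_estimates())
  expect_equal(ncol(tab), 2 + 4)
  expect_equal(nrow(tab), 31)
  expect_identical(tab$id[1], "1A")
  expect_identical(tab$id[nrow(tab)], "5C.2")
  # rounded report values, e.g. the Bangladesh seed requirement in MT
  expect_identical(tab[["Bangladesh rice"]][tab$id == "1D"], "349,249")
  expect_identical(tab[["Nigeria cassava"]][tab$id == "5C.2"], "17")

  one <- render_reach_table(estimate_reach(reach_fixture("pakistan_zinc_wheat_2023")))
  expect_equal(ncol(one), 3)

  empty <- render_reach_table(list())
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("id", "indicator"))
})

test_that("household size moves the farming population one for one", {
  res <- sensitivity_reach(reach_fixture("bangladesh_zinc_rice_2023"),
                           "3C", 10)
  farm <- res[res$quantity == "farming_population", ]
  expect_equal(farm$elasticity, rep(1, nrow(farm)), tolerance = 1e-9)
  # under full replacement the off-farm intake (246.9 kg/y) exceeds the
  # on-farm intake (187 kg/y), so shifting a tonne from market to farm adds
  # people on net: reach and coverage respond positively
  full <- res[res$scenario == "full replacement", ]
  expect_true(all(full$elasticity[full$quantity %in%
                                    c("reach", "coverage_pct")] > 0))
})

test_that("national intake trades off against the off-farm population", {
  res <- sensitivity_reach(reach_fixture("pakistan_zinc_wheat_2023"),
                           "4B", 10)
  off <- res[res$quantity == "offfarm_population", ]
  # fixed market quantity spread over a 10% higher intake: 1/1.1 - 1
  expect_equal(off$elasticity, rep((1 / 1.1 - 1) / 0.1, nrow(off)),
               tolerance = 1e-9)
  expect_true(all(res$elasticity[res$quantity == "reach"] < 0))
})

test_that("the national population feeds coverage but not reach", {
  res <- sensitivity_reach(reach_fixture("nigeria_vita_maize_2023"),
                           "5B", 10)
  expect_true(all(res$elasticity[res$quantity == "reach"] == 0))
  expect_true(all(res$elasticity[res$quantity == "coverage_pct"] < 0))
})

test_that("sensitivity elasticities match a direct finite-difference rerun", {
  cfg <- reach_fixture("nigeria_vita_cassava_2023")
  res <- sensitivity_reach(cfg, "3B", 5)
  est0 <- estimate_reach(cfg)
  est1 <- estimate_reach(perturb_config(cfg, "3B", 5))
  fd <- (est1$scenarios$reach - est0$scenarios$reach) /
    est0$scenarios$reach / 0.05
  expect_equal(res$elasticity[res$quantity == "reach"], fd, tolerance = 1e-12)
})

test_that("a perturbation that breaks the schema reports a violation row", {
  res <- sensitivity_reach(reach_fixture("bangladesh_zinc_rice_2023"),
                           "2F", 700)
  expect_true("violation" %in% names(res))
  expect_match(res$violation, "2F")
})

test_that("plot methods return ggplot objects", {
  est <- estimate_reach(reach_fixture("bangladesh_zinc_rice_2023"))
  expect_s3_class(autoplot(est), "ggplot")
  series <- project_growers(
    tibble::tibble(year = 2020:2023, households_acquiring = c(1, 2, 3, 4) * 1e5),
    diffusion = 0.1, attrition = 0.2)
  expect_s3_class(autoplot(series), "ggplot")
})

test_that("tidy and glance summarise an estimate", {
  est <- estimate_reach(reach_fixture("nigeria_vita_maize_2023"))
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("id", "label", "value", "unit"))
  gl <- glance(est)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$coverage_min_pct, 100 * gl$reach_min / 227882945)
  expect_identical(gl$country, "Nigeria")
})
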