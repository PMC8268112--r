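test_that("analysis runs are deterministic and write complete metadata", {
  cfg <- list(country = "finland", strategies = c("50-69", "45-69"),
              n_women = 1500, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  t1 <- run_screening_analysis(c(cfg, list(out_dir = d1)))
  t2 <- run_screening_analysis(c(cfg, list(out_dir = d2)))
  expect_identical(readLines(file.path(d1, "outcomes_finland.csv")),
                   readLines(file.path(d2, "outcomes_finland.csv")))
  expect_identical(readLines(file.path(d1, "outcomes_finland.json")),
                   readLines(file.path(d2, "outcomes_finland.json")))
  j <- jsonlite::read_json(file.path(d1, "outcomes_finland.json"))
  expect_equal(j$metadata$seed, 42)
  expect_equal(j$metadata$n_women, 1500)
  expect_true(nzchar(j$metadata$fixture_checksum))
  expect_true(nzchar(j$metadata$package_version))
  expect_equal(t1, t2)
})

test_that("bad configurations fail fast with field names", {
  expect_error(run_screening_analysis(list(country = "finland")),
               "n_women", class = "screensim_bad_config")
  d <- withr::local_tempdir()
  expect_error(
    run_screening_analysis(list(country = "finland", n_women = 10, seed = 1,
                                out_dir = d, strategies = "40-80x")),
    class = "screensim_bad_strategy"
  )
})

test_that("screens per woman order as the round counts 10 < 12.5 <= 12.5 < 15", {
  p <- country_fixture("finland")
  comp <- analyze_strategies(p, c("50-69", "45-74", "45-69", "50-74"),
                             n_women = 2e4, seed = 31)
  screens <- vapply(comp$scenarios, function(s) tidy(s)$per_1000[1], numeric(1))
  expect_lt(screens[["50-69"]], min(screens[["45-69"]], screens[["50-74"]]))
  expect_gt(screens[["45-74"]], max(screens[["45-69"]], screens[["50-74"]]))
  tab <- build_outcome_table(comp)
  expect_equal(tab$strategy, c("50-69", "45-74", "45-69", "50-74"))
  # reference row absolute, alternatives incremental: increments + reference
  # reproduce each strategy's own harms/benefits
  for (lab in c("45-74", "45-69", "50-74")) {
    cum <- cumulative_hb(comp$hb[["50-69"]],
                         harm_benefit(tab$overdiagnosed[tab$strategy == lab],
                                      tab$false_positives[tab$strategy == lab],
                                      tab$deaths_averted[tab$strategy == lab],
                                      tab$lyg[tab$strategy == lab]))
    expect_equal(unlist(cum[1, ]), unlist(comp$hb[[lab]][1, ]), tolerance = 1e-9)
  }
})

test_that("a reference compared with itself yields zero changes and a plot", {
  # non-progressive disease plus background mortality so that every ratio
  # numerator (overdiagnoses, false positives) is positive
  p <- toy_country(onset_lambda = 0.03, p_nonprog = 0.2,
                   life_q = c(rep(0.02, 55), 1))
  comp <- analyze_strategies(p, c("50-69", "45-69"), n_women = 5000, seed = 32)
  pct <- percent_change_table(comp)
  expect_equal(nrow(pct), 1)
  comp_self <- comp
  comp_self$hb[["45-69"]] <- comp$hb[["50-69"]]
  expect_true(all(unlist(percent_change_table(comp_self)[, -1]) == 0))
  gg <- ggplot2::autoplot(comp)
  expect_s3_class(gg, "ggplot")
})

test_that("replaying a published-style table reproduces its cumulative ratios", {
  pub <- published_screening_outcomes()
  fi <- build_outcome_table(pub[pub$country == "finland",
                               c("country", "strategy", "reference", "screens",
                                 "overdiagnosed", "false_positives",
                                 "deaths_averted", "lyg")])
  expect_equal(fi$od_per_da[fi$strategy == "50-74"], 0.4)
  expect_equal(fi$fp_per_da[fi$strategy == "50-74"], 25.9)
  expect_equal(fi$od_per_lyg[fi$strategy == "50-74"], 0.032)
  expect_equal(fi$fp_per_lyg[fi$strategy == "50-74"], 2.1)
  # round-trip: increments computed back from cumulative values
  cum <- cumulative_hb(
    harm_benefit(2.6, 212.3, 7.7, 105.3), harm_benefit(1.5, 135.6, 3.2, 38.8))
  expect_equal(cum$overdiagnosed - 2.6, 1.5)
  expect_error(build_outcome_table(pub[, 1:4]), class = "screensim_bad_params")
})

test_that("sensitivity variants move ratios in the expected direction", {
  p <- toy_country(onset_lambda = 0.04,
                   referral = c(under50 = 0.065, over50 = 0.058), name = "toyland")
  grid <- run_sensitivity_scenarios(
    countries = list(toyland = p), variants = "lowest_referral",
    strategies = "50-69", n_women = 5000, seed = 33
  )
  base <- grid[grid$variant == "base", ]
  low <- grid[grid$variant == "lowest_referral", ]
  expect_lt(low$fp_per_da, base$fp_per_da)
  expect_equal(low$od_per_da, base$od_per_da) # referral does not touch detection
  expect_equal(low$rel_fp_per_da, low$fp_per_da / base$fp_per_da)
})

test_that("the observed-coverage variant with 100% observed coverage is a no-op", {
  p <- toy_country(onset_lambda = 0.03) # observed coverage all 1 in the toy
  v <- variant_params(p, "observed_coverage")
  expect_identical(v, p)
  a <- run_scenario(p, "50-69", n_women = 2000, seed = 34)
  b <- run_scenario(v, "50-69", n_women = 2000, seed = 34)
  expect_identical(tidy(a), tidy(b))
})
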