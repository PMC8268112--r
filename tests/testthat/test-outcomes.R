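ZERO_SENS <- c(DCIS = 0, T1a = 0, T1b = 0, T1c = 0, T2plus = 0)

test_that("a disease-free cohort has life-table person-years and nothing else", {
  p <- toy_country(onset_lambda = 0, life_q = c(rep(0.02, 55), 1))
  sc <- run_scenario(p, NULL, n_women = 2e4, seed = 12)
  s <- tidy(sc)
  get <- function(o) s$per_1000[s$outcome == o]
  expect_equal(get("total_diagnosed"), 0)
  expect_equal(get("bc_deaths"), 0)
  exp_py <- (life_expectancy(p$life_table) - 45) * 1000
  expect_lt(abs(get("person_years") - exp_py), 3 * s$se[s$outcome == "person_years"])
})

test_that("with full attendance and no deaths, screens are exactly rounds x 1000", {
  p <- toy_country(onset_lambda = 0)
  sc <- run_scenario(p, "50-69", n_women = 2000, seed = 13)
  expect_equal(tidy(sc)$per_1000[tidy(sc)$outcome == "screens"], 10000)
})

test_that("zero-sensitivity screening yields exactly zero incremental outcomes", {
  p <- toy_country(onset_lambda = 0.03)
  h <- sample_histories(p, 5000, seed = 14)
  base <- screensim:::scenario_from_histories(h, NULL)
  scr <- screensim:::scenario_from_histories(
    h, strategy(50, 69), test = screening_test(ZERO_SENS, p$policy$referral))
  hb <- harms_benefits(scr, base)
  expect_identical(hb$overdiagnosed, 0)
  expect_identical(hb$deaths_averted, 0)
  expect_identical(hb$lyg, 0)
  expect_gt(hb$false_positives, 0)
})

test_that("paired per-woman records give the textbook harms and benefits", {
  # 3 women: one averted death (+12.0 years), one overdiagnosis, two FPs
  base_w <- tibble::tibble(
    id = 1:3, screens = 0L, fp = 0L,
    screen_dx_age = NA_real_, screen_dx_stage = NA_character_,
    dx_age = c(60, NA, NA), dx_stage = c("T2plus", NA, NA),
    bc_death = c(TRUE, FALSE, FALSE), death_age = c(68, 80, 85),
    death_cause = c("breast_cancer", "other", "other"),
    py = c(23, 35, 40)
  )
  scr_w <- base_w
  scr_w$screens <- 10L
  scr_w$fp <- c(1L, 1L, 0L)
  scr_w$screen_dx_age <- c(55, 60, NA)
  scr_w$dx_age <- c(55, 60, NA)
  scr_w$bc_death <- c(FALSE, FALSE, FALSE)
  scr_w$death_age <- c(80, 80, 85)
  scr_w$death_cause <- "other"
  scr_w$py <- c(35, 35, 40)

  base <- new_scenario_outcome(base_w, "none", seed = 1L, checksum = "x")
  scr <- new_scenario_outcome(scr_w, "50-69", seed = 1L, checksum = "x")
  hb <- harms_benefits(scr, base)
  expect_equal(hb$overdiagnosed, 1000 / 3)
  expect_equal(hb$false_positives, 2000 / 3)
  expect_equal(hb$deaths_averted, 1000 / 3)
  expect_equal(hb$lyg, 4000)

  labels <- overdiagnosis_labels(scr, base)
  expect_equal(labels$overdiagnosed, c(FALSE, TRUE, FALSE))

  self <- harms_benefits(base, base)
  expect_true(all(unlist(self[1, ]) == 0))
})

test_that("arms from different seeds or bundles are rejected as unpaired", {
  p <- toy_country(onset_lambda = 0.02)
  a <- run_scenario(p, "50-69", n_women = 500, seed = 1)
  b <- run_scenario(p, NULL, n_women = 500, seed = 2)
  expect_error(harms_benefits(a, b), class = "screensim_unpaired")
  b2 <- run_scenario(p, NULL, n_women = 400, seed = 1)
  expect_error(harms_benefits(a, b2), class = "screensim_unpaired")
})

test_that("ratio arithmetic and rounding reproduce published-style cells", {
  hb <- harm_benefit(2.6, 212.3, 7.7, 105.3)
  rs <- round_ratio_set(ratios(hb))
  expect_equal(unlist(rs), c(od_per_da = 0.3, fp_per_da = 27.6,
                             od_per_lyg = 0.025, fp_per_lyg = 2.0))
  rs2 <- round_ratio_set(ratios(harm_benefit(3.3, 275.8, 7.3, 96.5)))
  expect_equal(rs2$od_per_lyg, 0.034)
  # zero harms with positive benefits: all ratios zero
  rs3 <- ratios(harm_benefit(0, 0, 5, 50))
  expect_equal(unlist(rs3), c(od_per_da = 0, fp_per_da = 0, od_per_lyg = 0, fp_per_lyg = 0))
  # zero denominator: an undefined-ratio signal, not a number
  expect_error(ratios(harm_benefit(1, 2, 0, 50)), class = "screensim_undefined_ratio")
  expect_error(ratios(harm_benefit(1, 2, 5, 0)), class = "screensim_undefined_ratio")
})

test_that("cumulative values recover the alternative strategies' ratios", {
  ref <- harm_benefit(2.6, 212.3, 7.7, 105.3)
  inc <- harm_benefit(1.4, 48.8, 2.4, 19.4)
  cum <- cumulative_hb(ref, inc)
  expect_equal(unlist(cum[1, ]), c(overdiagnosed = 4.0, false_positives = 261.1,
                                   deaths_averted = 10.1, lyg = 124.7))
  expect_equal(unlist(round_ratio_set(ratios(cum))),
               c(od_per_da = 0.4, fp_per_da = 25.9, od_per_lyg = 0.032, fp_per_lyg = 2.1))
  # identity and commutativity
  zero <- harm_benefit(0, 0, 0, 0)
  expect_equal(unlist(cumulative_hb(ref, zero)[1, ]), unlist(ref[1, ]))
  set.seed(1)
  for (i in 1:5) {
    a <- harm_benefit(runif(1, 0, 5), runif(1, 0, 500), runif(1, 0, 15), runif(1, 0, 200))
    b <- harm_benefit(runif(1, 0, 5), runif(1, 0, 500), runif(1, 0, 15), runif(1, 0, 200))
    expect_equal(unlist(cumulative_hb(a, b)[1, ]), unlist(cumulative_hb(b, a)[1, ]))
  }
})

test_that("percent changes are signed relative differences", {
  ref <- ratios(harm_benefit(2.6, 212.3, 7.7, 105.3))
  expect_true(all(unlist(percent_change(ref, ref)) == 0))
  alt <- ref
  alt$od_per_lyg <- 0.023
  ref2 <- ref
  ref2$od_per_lyg <- 0.025
  expect_equal(percent_change(alt, ref2)$od_per_lyg, -8)
  alt$fp_per_da <- 20
  ref2$fp_per_da <- 10
  expect_equal(percent_change(alt, ref2)$fp_per_da, 100)
  ref0 <- ref
  ref0$od_per_da <- 0
  expect_error(percent_change(alt, ref0), class = "screensim_undefined_ratio")
})

test_that("per-1000 estimates are invariant to cohort size up to Monte Carlo noise", {
  p <- toy_country(onset_lambda = 0.03)
  comp1 <- analyze_strategies(p, "50-69", n_women = 5000, seed = 15)
  comp2 <- analyze_strategies(p, "50-69", n_women = 10000, seed = 16)
  hb1 <- comp1$hb[["50-69"]]
  hb2 <- comp2$hb[["50-69"]]
  se <- sqrt(attr(hb1, "se")^2 + attr(hb2, "se")^2)
  d <- abs(unlist(hb1[1, ]) - unlist(hb2[1, ]))
  expect_true(all(d <= 3 * se + 1e-9))
})
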