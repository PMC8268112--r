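test_that("identical seeds reproduce the cohort bit-for-bit", {
  p <- toy_country()
  h1 <- sample_histories(p, 500, seed = 99)
  h2 <- sample_histories(p, 500, seed = 99)
  expect_identical(h1$women, h2$women)
  expect_identical(h1$u_detect, h2$u_detect)
  h3 <- sample_histories(p, 500, seed = 100)
  expect_false(identical(h1$women, h3$women))
})

test_that("zero onset hazard means no disease at all", {
  p <- toy_country(onset_lambda = 0)
  h <- sample_histories(p, 2000, seed = 1)
  expect_true(all(is.na(h$women$onset_age)))
  expect_true(all(is.na(h$women$clinical_dx_age)))
})

test_that("fully non-progressive DCIS never surfaces clinically", {
  p <- toy_country(onset_lambda = 0.05, p_nonprog = 1)
  h <- sample_histories(p, 5000, seed = 2)
  w <- h$women
  expect_gt(sum(!is.na(w$onset_age)), 0)
  expect_true(all(w$nonprog[!is.na(w$onset_age)]))
  expect_true(all(is.na(w$clinical_dx_age)))
  expect_true(all(is.na(w$entry_T1a)))
})

test_that("clinical surfacing competes with progression as b/(a+b)", {
  a <- 0.4 # dwell (progression) rate in DCIS
  b <- 0.6 # clinical-surfacing hazard in DCIS
  # onset only from 45 so the alive-and-undiagnosed-at-45 conditioning does
  # not bias the race between surfacing and progression
  p <- toy_country(onset_lambda = 0.05, onset_from = 45,
                   dwell = c(DCIS = a, T1a = 1, T1b = 1, T1c = 1, T2plus = 0),
                   clin = c(DCIS = b, T1a = 0, T1b = 0, T1c = 0, T2plus = 0))
  h <- sample_histories(p, 1e5, seed = 3)
  w <- h$women[!is.na(h$women$onset_age) & !h$women$nonprog, ]
  # every onset either surfaces in DCIS or progresses to T1a
  surfaced <- !is.na(w$clinical_dx_age) & w$clinical_dx_stage == "DCIS"
  progressed <- !is.na(w$entry_T1a)
  expect_true(all(xor(surfaced, progressed)))
  phat <- mean(surfaced)
  ptrue <- b / (a + b)
  se <- sqrt(ptrue * (1 - ptrue) / nrow(w))
  expect_lt(abs(phat - ptrue), 3 * se)
})

test_that("cohort conditioning and conservation invariants hold", {
  p <- toy_country(life_q = c(rep(0.01, 55), 1), onset_lambda = 0.02)
  h <- sample_histories(p, 2e4, seed = 4)
  w <- h$women
  expect_true(all(is.na(w$clinical_dx_age) | w$clinical_dx_age >= 45))
  expect_true(all(w$ocd_age >= 45 & w$ocd_age < 101))
  entries <- as.matrix(w[, paste0("entry_", c("DCIS", "T1a", "T1b", "T1c", "T2plus"))])
  diffs <- t(apply(entries, 1, diff))
  expect_true(all(diffs > 0, na.rm = TRUE)) # stage entries strictly increasing
  # stage at clinical diagnosis: its entry age never exceeds the dx age
  dxed <- !is.na(w$clinical_dx_age)
  stage_col <- match(w$clinical_dx_stage[dxed], c("DCIS", "T1a", "T1b", "T1c", "T2plus"))
  expect_true(all(entries[cbind(which(dxed), stage_col)] <= w$clinical_dx_age[dxed]))

  out <- resolve_no_screening(h)
  expect_equal(nrow(out), nrow(w))
  expect_true(all(out$death_age <= 101))
  expect_true(all(out$death_cause %in% c("breast_cancer", "other")))
  expect_true(all(out$death_age[out$death_cause == "other"] == w$ocd_age[out$death_cause == "other"]))
})

test_that("no-screening resolution follows the competing-risk rules", {
  p <- toy_country()
  # diagnosis after other-cause death: never recorded
  h <- manual_histories(manual_woman(ocd_age = 70, onset_age = 60, entries = c(60, NA, NA, NA, NA),
                                     clinical_dx_age = 75, clinical_dx_stage = "DCIS"), p)
  out <- resolve_no_screening(h)
  expect_true(is.na(out$dx_age))
  expect_equal(out$death_cause, "other")
  expect_equal(out$death_age, 70)

  # universal cure: no breast-cancer deaths in a whole cohort
  p_cure <- toy_country(onset_lambda = 0.05, cure = toy_cure(1))
  h2 <- sample_histories(p_cure, 2e4, seed = 5)
  out2 <- resolve_no_screening(h2)
  expect_equal(sum(out2$bc_death), 0)

  # deterministic toy: dx at 60 in T2plus, cure 0, 5-year survival, ocd 80
  p0 <- toy_country(cure = toy_cure(0))
  u_five <- 1 - exp(-1) # qexp(u, rate = 1/5) == 5 exactly
  h3 <- manual_histories(manual_woman(ocd_age = 80, onset_age = 55,
                                      entries = c(55, 56, 57, 58, 59),
                                      clinical_dx_age = 60, clinical_dx_stage = "T2plus",
                                      u_survival = 0.9, u_ttd = u_five), p0)
  out3 <- resolve_no_screening(h3, survival = list(
    cure = toy_cure(0), ttd_mean = c(DCIS = 5, T1a = 5, T1b = 5, T1c = 5, T2plus = 5),
    screen_benefit = 1))
  expect_equal(out3$death_age, 65)
  expect_equal(out3$death_cause, "breast_cancer")
})

test_that("cohorts export to CSV with one row per woman", {
  p <- toy_country(onset_lambda = 0.02)
  h <- sample_histories(p, 50, seed = 17)
  path <- withr::local_tempfile(fileext = ".csv")
  write_history_cohort(h, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 50)
  expect_equal(names(back)[1:4], c("id", "ocd_age", "onset_age", "nonprog"))
  expect_equal(back$ocd_age, h$women$ocd_age)
})
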