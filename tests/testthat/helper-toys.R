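# Toy parameter bundles with analytically tractable behaviour, built in code.

# A life table from an explicit q vector (terminal q forced to 1).
toy_life_table <- function(q, start_age = 45L) {
  q[length(q)] <- 1
  tibble::tibble(age = seq.int(start_age, start_age + length(q) - 1L), q = q)
}

# Constant onset hazard from age `from`; zero before.
toy_onset <- function(lambda, ages = 20:100, from = 20) {
  tibble::tibble(age = as.integer(ages),
                 lambda = ifelse(ages >= from, lambda, 0))
}

toy_cure <- function(value = 0.5, by_stage = NULL) {
  stages <- c("DCIS", "T1a", "T1b", "T1c", "T2plus")
  groups <- c("45-49", "50-59", "60-69", "70plus")
  vals <- if (is.null(by_stage)) rep(value, 5) else by_stage[stages]
  matrix(rep(vals, 4), nrow = 5,
         dimnames = list(stages, groups))
}

# Fully parameterised toy country; defaults give a moderately active model.
toy_country <- function(life_q = c(rep(0, 55), 1),
                        onset_lambda = 0.004,
                        onset_from = 20,
                        p_nonprog = 0,
                        dwell = c(DCIS = 0.5, T1a = 1, T1b = 0.8, T1c = 0.6, T2plus = 0),
                        clin = c(DCIS = 0.03, T1a = 0.1, T1b = 0.25, T1c = 0.55, T2plus = 1.2),
                        cure = toy_cure(0.5),
                        ttd_mean = c(DCIS = 12, T1a = 10, T1b = 8, T1c = 6, T2plus = 4),
                        screen_benefit = 1.2,
                        sensitivity = c(DCIS = 0.7, T1a = 0.7, T1b = 0.7, T1c = 0.9, T2plus = 1),
                        referral = c(under50 = 0.03, over50 = 0.028),
                        coverage = rep(1, 6),
                        name = "toyland") {
  country_params(
    name = name,
    life_table = toy_life_table(life_q),
    onset = toy_onset(onset_lambda, from = onset_from),
    natural_history = list(p_nonprogressive_dcis = p_nonprog,
                           dwell_rates = dwell, clinical_hazards = clin),
    survival = list(cure = cure, ttd_mean = ttd_mean, screen_benefit = screen_benefit),
    policy = list(sensitivity = sensitivity, referral = referral,
                  coverage = coverage, observed_coverage = coverage)
  )
}

# A life_histories object built by hand (for deterministic resolver checks).
manual_histories <- function(women, params, seed = 0L) {
  n <- nrow(women)
  structure(
    list(women = women,
         u_attend = matrix(0.5, n, 16), u_detect = matrix(0.5, n, 16),
         u_fp = matrix(0.5, n, 16),
         params = params, seed = as.integer(seed), n = n),
    class = "life_histories"
  )
}

manual_woman <- function(ocd_age, onset_age = NA_real_, nonprog = FALSE,
                         entries = rep(NA_real_, 5),
                         clinical_dx_age = NA_real_, clinical_dx_stage = NA_character_,
                         u_survival = 0.5, u_ttd = 0.5, phase = 0L, id = 1L) {
  tibble::tibble(
    id = id, ocd_age = ocd_age, onset_age = onset_age, nonprog = nonprog,
    entry_DCIS = entries[1], entry_T1a = entries[2], entry_T1b = entries[3],
    entry_T1c = entries[4], entry_T2plus = entries[5],
    clinical_dx_age = clinical_dx_age, clinical_dx_stage = clinical_dx_stage,
    u_survival = u_survival, u_ttd = u_ttd, phase = phase
  )
}

# The enumerable three-age toy: everyone (who gets cancer) has onset at ~45,
# a single effective stage (DCIS never progresses), other-cause death in
# [47, 48), one screen at age 46, and every free probability equal to 1/2.
enum_toy_country <- function() {
  toy_country(
    life_q = c(0, 0, 1),
    onset_lambda = 0, # replaced below
    p_nonprog = 0.5,
    dwell = c(DCIS = 1e-12, T1a = 1, T1b = 1, T1c = 1, T2plus = 0),
    clin = c(DCIS = log(2), T1a = 0, T1b = 0, T1c = 0, T2plus = 0),
    cure = toy_cure(0.5),
    ttd_mean = c(DCIS = 1e-9, T1a = 1e-9, T1b = 1e-9, T1c = 1e-9, T2plus = 1e-9),
    screen_benefit = 2,
    sensitivity = c(DCIS = 0.5, T1a = 0, T1b = 0, T1c = 0, T2plus = 0),
    referral = c(under50 = 0.5, over50 = 0.5)
  ) |> (function(p) {
    p$onset <- tibble::tibble(age = 45:47, lambda = c(1e9, 0, 0))
    p
  })()
}

enum_toy_strategy <- function() strategy(46, 47, interval = 2, phase_randomized = FALSE)

# Exact outcome expectations for the enumerable toy, per 1000 women.
# The discrete outcome tree (non-progressive vs progressive; attended;
# detected/missed; referred; cured/fatal, every free probability 1/2) is
# enumerated exhaustively; within branches, the exponential surfacing time
# T ~ Exp(log 2) from onset (age 45) and the uniform within-year
# other-cause death time V (death at age 47 + V) are integrated on a dense
# grid. The single screen is at age 46; breast-cancer death follows
# diagnosis immediately (time-to-death ~ 0), so a fatal diagnosed woman
# dies at 45 + T and any other woman at 47 + V (person-years measured
# from age 45: T, respectively 2 + V).
enum_toy_expectations <- function() {
  nt <- 20000
  tg <- seq(0, 40, length.out = nt + 1) # T support, tail mass 2^-40
  tm <- (tg[-1] + tg[-(nt + 1)]) / 2
  w_t <- log(2) * 2^(-tm) * diff(tg)    # P(T in cell)
  nv <- 400
  vm <- (seq_len(nv) - 0.5) / nv
  w_v <- rep(1 / nv, nv)
  EV <- 2.5                             # E[2 + V]

  dx <- outer(tm, 2 + vm, `<`)          # diagnosed before other-cause death
  py_if_fatal <- dx * tm + (!dx) * outer(rep(1, nt), 2 + vm)
  lt1 <- tm < 1

  P1 <- sum(w_t[lt1])                             # T < 1: surfaces before the screen
  A_lt1 <- sum(w_t[lt1] * tm[lt1])                # E[T ; T < 1] (dx certain there)
  P_dx_ge1 <- as.numeric(t(w_t[!lt1]) %*% dx[!lt1, , drop = FALSE] %*% w_v)
  py_fatal_ge1 <- as.numeric(t(w_t[!lt1]) %*% py_if_fatal[!lt1, , drop = FALSE] %*% w_v)
  P_dx <- P1 + P_dx_ge1
  py_fatal <- A_lt1 + py_fatal_ge1

  h <- 0.5
  base <- list(
    screens = 0,
    screen_detected = 0,
    clinically_detected = h * P_dx,
    total_diagnosed = h * P_dx,
    fp = 0,
    bc_deaths = h * h * P_dx,
    person_years = h * EV + h * (h * EV + h * py_fatal)
  )

  screens <- h * 1 + h * (1 - P1)       # nonprog always; progressive iff T >= 1
  screen_detected <- h * h + h * (1 - P1) * h
  clinically_detected <- h * (P1 + h * P_dx_ge1)
  scr <- list(
    screens = screens,
    screen_detected = screen_detected,
    clinically_detected = clinically_detected,
    total_diagnosed = screen_detected + clinically_detected,
    fp = screens * h * h,               # every attended screen: missed (1/2) then referred (1/2)
    bc_deaths = h * (h * P1 + h * h * P_dx_ge1),
    person_years = h * EV + h * (
      h * P1 * EV + h * A_lt1 +         # T < 1: cured / fatal, as baseline
      (1 - P1) * h * EV +               # T >= 1, detected: cured (benefit lifts cure to 1)
      h * (1 - P1) * h * EV +           # T >= 1, missed, cured
      h * h * py_fatal_ge1              # T >= 1, missed, fatal
    )
  )
  list(base = lapply(base, function(x) x * 1000),
       screened = lapply(scr, function(x) x * 1000))
}

fold01_for_test <- function(x) screensim:::fold01(x)
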