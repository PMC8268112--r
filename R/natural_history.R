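#' Sample a cohort of life histories
#'
#' Generates the no-screening disease course of `n` women aged 45 from a
#' country parameter bundle, with every stochastic draw a screening overlay
#' will later need (attendance, detection and referral uniforms, the
#' survival quantile) pre-sampled and stored alongside the history. The
#' screening arm therefore reuses the identical randomness (common random
#' numbers), which makes incremental outcomes exact at the woman level.
#'
#' All draws come from one seeded stream in a fixed, documented order, so a
#' second call with the same `(params, n, seed)` reproduces the cohort
#' bit-for-bit. Women with a clinical diagnosis before age 45 are discarded
#' and redrawn, so the cohort is "n women aged 45, alive and undiagnosed".
#'
#' @param params A [country_params()] bundle.
#' @param n Number of women.
#' @param seed Integer master seed.
#' @return A `life_histories` object: a list with `women` (one row per
#'   woman, see Details), uniform matrices `u_attend`, `u_detect`, `u_fp`
#'   (`n` x 16 reserved screening-round draws), the originating `params`,
#'   `seed` and `n`.
#'
#' @details The `women` tibble has columns `id`, `ocd_age` (other-cause
#' death age), `onset_age` (`NA` when no preclinical onset), `nonprog`
#' (non-progressive DCIS flag), `entry_DCIS` .. `entry_T2plus` (stage entry
#' ages, `NA` beyond the progression stop), `clinical_dx_age` /
#' `clinical_dx_stage` (symptomatic surfacing, `NA` when the tumour never
#' surfaces), `u_survival` and `u_ttd` (quantiles reserved for survival
#' coupling) and `phase` (0/1-year screening offset).
#' @export
sample_histories <- function(params, n, seed) {
  if (!inherits(params, "country_params")) {
    abort("`params` must be a country_params bundle", class = "screensim_bad_params")
  }
  if (n < 1) abort("`n` must be >= 1", class = "screensim_bad_params")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  block <- draw_history_block(params, n)
  # Redraw women diagnosed before 45: the cohort is conditioned on being
  # alive and undiagnosed at 45 (other-cause deaths already are, since the
  # life table starts at 45).
  repeat {
    bad <- which(!is.na(block$women$clinical_dx_age) & block$women$clinical_dx_age < 45)
    if (length(bad) == 0L) break
    repl <- draw_history_block(params, length(bad))
    block$women[bad, setdiff(names(block$women), "id")] <-
      repl$women[, setdiff(names(repl$women), "id")]
    block$u_attend[bad, ] <- repl$u_attend
    block$u_detect[bad, ] <- repl$u_detect
    block$u_fp[bad, ] <- repl$u_fp
  }
  structure(
    list(women = block$women, u_attend = block$u_attend,
         u_detect = block$u_detect, u_fp = block$u_fp,
         params = params, seed = as.integer(seed), n = as.integer(n)),
    class = "life_histories"
  )
}

# One batch of n complete histories, consuming the current RNG stream in a
# fixed order: ocd, onset, non-progression, dwell exponentials (5 stages),
# clinical-surfacing exponentials (5 stages), u_survival, u_ttd, phase,
# then the three n x 16 screening-round matrices.
draw_history_block <- function(params, n) {
  u_ocd <- stats::runif(n)
  e_onset <- stats::rexp(n)
  u_nonprog <- stats::runif(n)
  e_dwell <- matrix(stats::rexp(n * 5L), n, 5L)
  e_clin <- matrix(stats::rexp(n * 5L), n, 5L)
  u_survival <- stats::runif(n)
  u_ttd <- stats::runif(n)
  phase <- as.integer(stats::runif(n) < 0.5)
  u_attend <- matrix(stats::runif(n * MAX_ROUNDS), n, MAX_ROUNDS)
  u_detect <- matrix(stats::runif(n * MAX_ROUNDS), n, MAX_ROUNDS)
  u_fp <- matrix(stats::runif(n * MAX_ROUNDS), n, MAX_ROUNDS)

  ocd_age <- sample_other_cause_death(params$life_table, u = u_ocd)
  onset_age <- invert_onset(params$onset, e_onset)
  nh <- params$natural_history
  nonprog <- !is.na(onset_age) & (u_nonprog < nh$p_nonprogressive_dcis)

  course <- progress_stages(onset_age, nonprog, nh, e_dwell, e_clin)

  women <- tibble(
    id = seq_len(n),
    ocd_age = ocd_age,
    onset_age = onset_age,
    nonprog = nonprog,
    entry_DCIS = course$entry[, 1L],
    entry_T1a = course$entry[, 2L],
    entry_T1b = course$entry[, 3L],
    entry_T1c = course$entry[, 4L],
    entry_T2plus = course$entry[, 5L],
    clinical_dx_age = course$dx_age,
    clinical_dx_stage = course$dx_stage,
    u_survival = u_survival,
    u_ttd = u_ttd,
    phase = phase
  )
  list(women = women, u_attend = u_attend, u_detect = u_detect, u_fp = u_fp)
}

# Invert the piecewise-constant annual onset hazard with a unit
# exponential: onset falls in the year where the cumulative hazard first
# exceeds the draw, linearly interpolated within the year; NA when the
# total hazard is never reached (no onset in the lifetime of the table).
invert_onset <- function(onset, e) {
  cumH <- cumsum(onset$lambda)
  total <- cumH[length(cumH)]
  out <- rep(NA_real_, length(e))
  hit <- e < total
  if (any(hit)) {
    idx <- findInterval(e[hit], cumH, left.open = FALSE) + 1L
    lo <- c(0, cumH)[idx]
    out[hit] <- onset$age[idx] + (e[hit] - lo) / onset$lambda[idx]
  }
  out
}

# Semi-Markov progression through DCIS -> T1a -> T1b -> T1c -> T2plus.
# Within each stage an exponential clinical-surfacing clock competes with
# an exponential dwell (progression) clock, both restarted at stage entry;
# the first to ring wins. T2plus is terminal: no further progression.
# Non-progressive DCIS has both clocks switched off.
progress_stages <- function(onset_age, nonprog, nh, e_dwell, e_clin) {
  n <- length(onset_age)
  rates <- nh$dwell_rates[STAGES]
  hazards <- nh$clinical_hazards[STAGES]
  entry <- matrix(NA_real_, n, 5L)
  entry[, 1L] <- onset_age
  dx_age <- rep(NA_real_, n)
  dx_stage <- rep(NA_character_, n)
  active <- !is.na(onset_age) & !nonprog
  for (k in 1:5) {
    in_stage <- active & !is.na(entry[, k]) & is.na(dx_age)
    if (!any(in_stage)) break
    dwell <- if (k < 5 && rates[k] > 0) e_dwell[, k] / rates[k] else rep(Inf, n)
    t_clin <- if (hazards[k] > 0) e_clin[, k] / hazards[k] else rep(Inf, n)
    surfaces <- in_stage & t_clin < dwell
    dx_age[surfaces] <- entry[surfaces, k] + t_clin[surfaces]
    dx_stage[surfaces] <- STAGES[k]
    if (k < 5) {
      progresses <- in_stage & !surfaces & is.finite(dwell)
      entry[progresses, k + 1L] <- entry[progresses, k] + dwell[progresses]
    }
  }
  list(entry = entry, dx_age = dx_age, dx_stage = dx_stage)
}

#' @export
print.life_histories <- function(x, ...) {
  cat("<life_histories> ", x$n, " women, country ", x$params$name,
      ", seed ", x$seed, "\n", sep = "")
  cat("  onsets: ", sum(!is.na(x$women$onset_age)),
      "; clinical surfacing events: ", sum(!is.na(x$women$clinical_dx_age)),
      "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.life_histories <- function(x, ...) x$women

#' Write a life-history cohort to CSV
#'
#' One row per woman, for inspection outside R. Column order: `id`,
#' `ocd_age`, `onset_age`, `nonprog`, the five stage entry ages
#' (`entry_DCIS` .. `entry_T2plus`), `clinical_dx_age`, `clinical_dx_stage`,
#' `u_survival`, `u_ttd`, `phase`. The reserved screening-round uniforms are
#' not exported; regenerate the cohort from its seed to recover them.
#'
#' @param histories A [sample_histories()] cohort.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history_cohort <- function(histories, path) {
  if (!inherits(histories, "life_histories")) {
    abort("`histories` must come from sample_histories()", class = "screensim_bad_params")
  }
  readr::write_csv(histories$women, path)
  invisible(path)
}

# Cure probability at diagnosis for given stages (character) and ages.
cure_at <- function(survival, stage, age) {
  survival$cure[cbind(stage_index(stage), cure_age_group_index(age))]
}

#' Resolve the no-screening outcome of each life history
#'
#' Follows each woman's latent history without any screening: a clinical
#' diagnosis is recorded if the tumour surfaces before other-cause death;
#' she dies of breast cancer iff her shared survival quantile exceeds the
#' cure probability for her stage and age group at diagnosis and the
#' sampled time to breast-cancer death ends before her other-cause death.
#'
#' @param histories A [sample_histories()] cohort.
#' @param survival Optional survival model; defaults to the cohort's own.
#' @return A tibble with one row per woman: `id`, `dx_age`, `dx_stage`,
#'   `cure_prob`, `bc_death` (logical), `bc_death_age`, `death_age`,
#'   `death_cause` (`"breast_cancer"`/`"other"`) and `py` (person-years
#'   lived from age 45).
#' @export
resolve_no_screening <- function(histories, survival = NULL) {
  if (!inherits(histories, "life_histories")) {
    abort("`histories` must come from sample_histories()", class = "screensim_bad_params")
  }
  survival <- survival %||% histories$params$survival
  validate_survival(survival)
  w <- histories$women
  diagnosed <- !is.na(w$clinical_dx_age) & w$clinical_dx_age < w$ocd_age
  dx_age <- ifelse(diagnosed, w$clinical_dx_age, NA_real_)
  dx_stage <- ifelse(diagnosed, w$clinical_dx_stage, NA_character_)

  cure <- rep(NA_real_, nrow(w))
  cure[diagnosed] <- cure_at(survival, dx_stage[diagnosed], dx_age[diagnosed])
  fatal <- diagnosed & (w$u_survival > cure) & !is.na(cure)

  ttd <- rep(NA_real_, nrow(w))
  if (any(fatal)) {
    rate <- 1 / survival$ttd_mean[dx_stage[fatal]]
    ttd[fatal] <- stats::qexp(w$u_ttd[fatal], rate = rate)
  }
  bc_candidate <- dx_age + ttd
  bc_death <- fatal & !is.na(bc_candidate) & bc_candidate < w$ocd_age
  death_age <- ifelse(bc_death, bc_candidate, w$ocd_age)

  tibble(
    id = w$id,
    dx_age = dx_age,
    dx_stage = dx_stage,
    cure_prob = cure,
    bc_death = bc_death,
    bc_death_age = ifelse(bc_death, bc_candidate, NA_real_),
    death_age = death_age,
    death_cause = ifelse(bc_death, "breast_cancer", "other"),
    py = death_age - 45
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
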