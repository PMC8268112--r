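#' Define a screening strategy
#'
#' @param start_age,stop_age First and last invitation ages (years).
#' @param interval Years between rounds (2 for all standard strategies).
#' @param phase_randomized When `TRUE`, each woman's schedule is offset by
#'   0 or 1 year with probability 1/2. This reproduces fractional expected
#'   round counts such as 12.5 for 45-69: phase 0 gives 13 rounds, phase 1
#'   gives 12.
#' @return A `strategy` object.
#' @examples
#' build_schedule(strategy(50, 69), phase = 0)
#' @export
strategy <- function(start_age, stop_age, interval = 2, phase_randomized = TRUE) {
  if (!is.finite(start_age) || !is.finite(stop_age) || stop_age <= start_age) {
    abort("need start_age < stop_age", class = "screensim_bad_strategy")
  }
  if (interval <= 0) abort("interval must be positive", class = "screensim_bad_strategy")
  structure(
    list(start_age = start_age, stop_age = stop_age, interval = interval,
         phase_randomized = isTRUE(phase_randomized),
         label = paste0(start_age, "-", stop_age)),
    class = "strategy"
  )
}

#' Parse a strategy label such as "50-69"
#'
#' @param label Character label `"<start>-<stop>"`.
#' @param ... Passed to [strategy()].
#' @return A `strategy` object.
#' @export
parse_strategy_label <- function(label, ...) {
  m <- regmatches(label, regexec("^([0-9]+)-([0-9]+)$", label))[[1]]
  if (length(m) != 3L) {
    abort(paste0("cannot parse strategy label '", label,
                 "': expected '<start>-<stop>', e.g. '50-69'"),
          class = "screensim_bad_strategy")
  }
  strategy(as.numeric(m[2]), as.numeric(m[3]), ...)
}

#' Screening-round schedule for one phase
#'
#' @param strategy A [strategy()].
#' @param phase Woman-level offset in years (0 or 1).
#' @return Numeric vector of screening ages
#'   `start_age + phase, start_age + phase + interval, ... <= stop_age`.
#' @export
build_schedule <- function(strategy, phase = 0) {
  stopifnot(inherits(strategy, "strategy"))
  ages <- seq(strategy$start_age + phase, strategy$stop_age, by = strategy$interval)
  ages[ages <= strategy$stop_age]
}

#' Expected number of rounds under phase randomization
#'
#' Mean of the phase-0 and phase-1 round counts when the strategy
#' randomizes phase, otherwise the phase-0 count.
#'
#' @param strategy A [strategy()].
#' @return Expected rounds per woman (possibly fractional, e.g. 12.5).
#' @export
expected_rounds <- function(strategy) {
  n0 <- length(build_schedule(strategy, 0))
  if (!strategy$phase_randomized) return(n0)
  (n0 + length(build_schedule(strategy, 1))) / 2
}

#' Screening-test parameters
#'
#' @param sensitivity Probability of screen detection given a preclinical
#'   tumour, named by stage (DCIS, T1a, T1b, T1c, T2plus).
#' @param referral Probability that a screen without screen detection is
#'   referred for assessment (a false positive), named `under50` (screens
#'   strictly below age 50) and `over50` (age 50 and above).
#' @return A `screening_test` object.
#' @export
screening_test <- function(sensitivity, referral) {
  obj <- list(sensitivity = sensitivity, referral = referral)
  validate_policy(c(obj, list(coverage = rep(1, length(COVERAGE_GROUPS)))))
  structure(obj, class = "screening_test")
}

# The detection pass: walks the schedule and returns per-woman screen
# counts, false positives and the first screen-detection event. Survival is
# not touched, so calibration objectives can call this directly.
screening_rounds <- function(histories, strategy, test, coverage) {
  w <- histories$women
  n <- nrow(w)
  phase <- if (strategy$phase_randomized) w$phase else rep(0L, n)
  n_rounds <- length(build_schedule(strategy, 0))
  if (n_rounds > MAX_ROUNDS) {
    abort("strategy has more rounds than the reserved per-woman draws (16)",
          class = "screensim_bad_strategy")
  }
  entry <- as.matrix(w[, paste0("entry_", STAGES)])
  clin_dx <- ifelse(is.na(w$clinical_dx_age), Inf, w$clinical_dx_age)
  onset <- w$onset_age
  has_onset <- !is.na(onset)
  sens <- test$sensitivity[STAGES]
  refer <- test$referral

  screens <- integer(n)
  fp <- integer(n)
  det_age <- rep(NA_real_, n)
  det_stage_idx <- rep(NA_integer_, n)
  undetected <- rep(TRUE, n)

  for (r in seq_len(n_rounds)) {
    age_r <- strategy$start_age + phase + strategy$interval * (r - 1)
    eligible <- age_r <= strategy$stop_age & age_r < w$ocd_age &
      age_r < clin_dx & undetected
    if (!any(eligible)) next
    p_att <- coverage[coverage_group_index(age_r)]
    attends <- eligible & histories$u_attend[, r] < p_att
    screens <- screens + attends
    present <- attends & has_onset & onset <= age_r
    stage_idx <- rep(NA_integer_, n)
    if (any(present)) {
      sub <- entry[present, , drop = FALSE]
      stage_idx[present] <- rowSums(!is.na(sub) & sub <= age_r[present])
    }
    detect <- present & histories$u_detect[, r] < sens[stage_idx]
    detect[is.na(detect)] <- FALSE
    det_age[detect] <- age_r[detect]
    det_stage_idx[detect] <- stage_idx[detect]
    undetected[detect] <- FALSE
    p_ref <- ifelse(age_r < 50, refer[["under50"]], refer[["over50"]])
    fp <- fp + (attends & !detect & histories$u_fp[, r] < p_ref)
  }
  list(screens = as.integer(screens), fp = as.integer(fp),
       det_age = det_age, det_stage_idx = det_stage_idx)
}

#' Overlay a screening strategy on shared life histories
#'
#' Walks each woman's screening schedule: a round happens only while she is
#' alive and not yet diagnosed; she attends with the age-group coverage
#' probability; if a preclinical tumour is present its current stage's
#' sensitivity decides detection; an attended screen without detection is a
#' false-positive referral with the age-band referral probability. On
#' screen detection, survival is re-resolved with the same per-woman
#' survival quantile and the cure probability of the earlier detected
#' stage, multiplied by `screen_benefit` (clamped to 1 and floored at the
#' clinical-diagnosis cure), so screening can avert but never cause a
#' breast-cancer death, and never moves a death earlier.
#'
#' @param histories A [sample_histories()] cohort.
#' @param strategy A [strategy()].
#' @param test Optional [screening_test()]; default from the cohort params.
#' @param coverage Optional per-age-group attendance probabilities; default
#'   from the cohort params (all 1 under the 100%-coverage assumption).
#' @param survival Optional survival model; default from the cohort params.
#' @return A tibble with one row per woman: screens attended, false
#'   positives, screen/clinical diagnosis, death age and cause, and
#'   person-years from 45.
#' @export
run_screening_arm <- function(histories, strategy, test = NULL,
                              coverage = NULL, survival = NULL) {
  if (!inherits(histories, "life_histories")) {
    abort("`histories` must come from sample_histories()", class = "screensim_bad_params")
  }
  stopifnot(inherits(strategy, "strategy"))
  pol <- histories$params$policy
  test <- test %||% screening_test(pol$sensitivity, pol$referral)
  coverage <- coverage %||% pol$coverage
  survival <- survival %||% histories$params$survival
  validate_survival(survival)
  if (length(coverage) != length(COVERAGE_GROUPS) || any(coverage < 0 | coverage > 1)) {
    abort("`coverage` must give one probability per age group", class = "screensim_bad_params")
  }

  base <- resolve_no_screening(histories, survival)
  w <- histories$women
  n <- nrow(w)
  rounds <- screening_rounds(histories, strategy, test, coverage)
  screens <- rounds$screens
  fp <- rounds$fp
  det_age <- rounds$det_age
  det_stage_idx <- rounds$det_stage_idx

  detected <- !is.na(det_age)
  det_stage <- ifelse(detected, STAGES[det_stage_idx], NA_character_)

  # Coupled survival: boosted cure at the detected stage, floored at the
  # clinical-diagnosis cure; a breast-cancer death happens only if it also
  # happened in the baseline arm, and then at the same age (lead time does
  # not move the date of death).
  cure2 <- rep(NA_real_, n)
  if (any(detected)) {
    cure2[detected] <- pmin(1, cure_at(survival, det_stage[detected], det_age[detected]) *
                                 survival$screen_benefit)
    has_base_cure <- detected & !is.na(base$cure_prob)
    cure2[has_base_cure] <- pmax(cure2[has_base_cure], base$cure_prob[has_base_cure])
  }
  bc_death <- base$bc_death & (!detected | (w$u_survival > cure2))
  death_age <- ifelse(bc_death, base$bc_death_age, w$ocd_age)

  dx_age <- ifelse(detected, det_age, base$dx_age)
  dx_stage <- ifelse(detected, det_stage, base$dx_stage)

  tibble(
    id = w$id,
    screens = as.integer(screens),
    fp = as.integer(fp),
    screen_dx_age = det_age,
    screen_dx_stage = det_stage,
    dx_age = dx_age,
    dx_stage = dx_stage,
    bc_death = bc_death,
    death_age = death_age,
    death_cause = ifelse(bc_death, "breast_cancer", "other"),
    py = death_age - 45
  )
}
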