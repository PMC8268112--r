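#' Simulate one screening scenario
#'
#' Generates `n_women` life histories from the master seed and overlays the
#' given strategy (or none). Outcomes are normalized per 1000 women aged 45
#' and carry Monte Carlo standard errors. Because the seed fully determines
#' the histories, two scenarios run with the same `(params, n_women, seed)`
#' share every woman's latent disease course and random draws, and can be
#' compared woman-by-woman with [harms_benefits()].
#'
#' @param params A [country_params()] bundle.
#' @param strategy A [strategy()], a label such as `"50-69"`, or `NULL` for
#'   the no-screening arm.
#' @param n_women Cohort size.
#' @param seed Master seed.
#' @param test,coverage,survival Optional overrides passed to
#'   [run_screening_arm()].
#' @return A `scenario_outcome` object; see [tidy.scenario_outcome()].
#' @export
run_scenario <- function(params, strategy = NULL, n_women, seed,
                         test = NULL, coverage = NULL, survival = NULL) {
  if (is.character(strategy)) strategy <- parse_strategy_label(strategy)
  histories <- sample_histories(params, n_women, seed)
  scenario_from_histories(histories, strategy, test, coverage, survival)
}

# Split out so calibration can reuse one cohort across many overlays.
scenario_from_histories <- function(histories, strategy = NULL, test = NULL,
                                    coverage = NULL, survival = NULL) {
  if (is.null(strategy)) {
    base <- resolve_no_screening(histories, survival)
    women <- tibble(
      id = base$id, screens = 0L, fp = 0L,
      screen_dx_age = NA_real_, screen_dx_stage = NA_character_,
      dx_age = base$dx_age, dx_stage = base$dx_stage,
      bc_death = base$bc_death, death_age = base$death_age,
      death_cause = base$death_cause, py = base$py
    )
    label <- "none"
  } else {
    women <- run_screening_arm(histories, strategy, test, coverage, survival)
    label <- strategy$label
  }
  new_scenario_outcome(women, label = label, n_women = histories$n,
                       seed = histories$seed, country = histories$params$name,
                       checksum = digest::digest(histories$params))
}

#' Assemble a scenario outcome from per-woman records
#'
#' Low-level constructor, mainly for tests and for replaying externally
#' stored per-woman records. `women` needs columns `id`, `screens`, `fp`,
#' `screen_dx_age`, `dx_age`, `bc_death`, `death_age`, `py`.
#'
#' @param women Per-woman record tibble.
#' @param label Strategy label.
#' @param n_women,seed Cohort size and master seed (for pairing checks).
#' @param country,checksum Provenance fields.
#' @return A `scenario_outcome`.
#' @export
new_scenario_outcome <- function(women, label, n_women = nrow(women),
                                 seed = NA_integer_, country = NA_character_,
                                 checksum = NA_character_) {
  women <- as_tibble(women)
  n <- n_women
  per_woman <- tibble(
    outcome = c("screens", "screen_detected", "clinically_detected",
                "total_diagnosed", "fp", "bc_deaths", "person_years"),
  )
  vals <- list(
    screens = women$screens,
    screen_detected = as.numeric(!is.na(women$screen_dx_age)),
    clinically_detected = as.numeric(!is.na(women$dx_age) & is.na(women$screen_dx_age)),
    total_diagnosed = as.numeric(!is.na(women$dx_age)),
    fp = women$fp,
    bc_deaths = as.numeric(women$bc_death),
    person_years = women$py
  )
  summary <- tibble(
    outcome = names(vals),
    per_1000 = unname(vapply(vals, function(v) mean(v) * 1000, numeric(1))),
    se = unname(vapply(vals, function(v) stats::sd(v) / sqrt(n) * 1000, numeric(1)))
  )
  structure(
    list(summary = summary, women = women, label = label,
         n_women = as.integer(n), seed = seed, country = country,
         checksum = checksum),
    class = "scenario_outcome"
  )
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat("<scenario_outcome> strategy ", x$label, ", country ", x$country,
      ", n = ", x$n_women, ", seed ", x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scenario outcome
#'
#' @param x A `scenario_outcome`.
#' @param ... Unused.
#' @return Tibble with `outcome`, `per_1000` and Monte Carlo `se`.
#' @export
tidy.scenario_outcome <- function(x, ...) x$summary

#' @export
glance.scenario_outcome <- function(x, ...) {
  tibble(strategy = x$label, country = x$country, n_women = x$n_women,
         seed = x$seed, checksum = x$checksum)
}

scenario_value <- function(x, outcome) {
  x$summary$per_1000[match(outcome, x$summary$outcome)]
}

check_paired <- function(screened, baseline) {
  if (!inherits(screened, "scenario_outcome") || !inherits(baseline, "scenario_outcome")) {
    abort("both arms must be scenario_outcome objects", class = "screensim_bad_params")
  }
  if (screened$n_women != baseline$n_women) {
    abort("arms differ in n_women; they are not paired", class = "screensim_unpaired")
  }
  same_seed <- identical(screened$seed, baseline$seed)
  same_sum <- identical(screened$checksum, baseline$checksum)
  if (!isTRUE(same_seed) || !isTRUE(same_sum)) {
    abort("arms were simulated from different seeds or parameter bundles",
          class = "screensim_unpaired")
  }
  invisible(TRUE)
}

new_harm_benefit <- function(est, se, meta = list()) {
  out <- tibble(
    overdiagnosed = est[["overdiagnosed"]],
    false_positives = est[["false_positives"]],
    deaths_averted = est[["deaths_averted"]],
    lyg = est[["lyg"]]
  )
  structure(out, se = se, meta = meta,
            class = c("harm_benefit", class(out)))
}

#' Construct a harm/benefit row from known values
#'
#' For replaying published or externally computed harms and benefits
#' through [ratios()], [cumulative_hb()] and the table builders.
#'
#' @param overdiagnosed,false_positives,deaths_averted,lyg Per-1000 values.
#' @return A `harm_benefit` row (standard errors unknown, `NA`).
#' @export
harm_benefit <- function(overdiagnosed, false_positives, deaths_averted, lyg) {
  est <- c(overdiagnosed = overdiagnosed, false_positives = false_positives,
           deaths_averted = deaths_averted, lyg = lyg)
  new_harm_benefit(est, stats::setNames(rep(NA_real_, 4), names(est)))
}

#' Incremental harms and benefits of screening
#'
#' Compares two paired arms woman-by-woman: overdiagnoses are the
#' difference in total diagnosed cancers under lifelong follow-up, deaths
#' averted the difference in breast-cancer deaths, life-years gained the
#' difference in person-years, and false positives the difference in
#' referral counts (equal to the screened arm's false positives when the
#' baseline is no screening). All per 1000 women; Monte Carlo standard
#' errors come from the per-woman paired differences.
#'
#' @param screened,baseline Paired `scenario_outcome` objects (same
#'   parameters, `n_women` and seed).
#' @return A `harm_benefit` one-row tibble with columns `overdiagnosed`,
#'   `false_positives`, `deaths_averted`, `lyg`; standard errors in
#'   `attr(, "se")`.
#' @export
harms_benefits <- function(screened, baseline) {
  check_paired(screened, baseline)
  s <- screened$women[order(screened$women$id), ]
  b <- baseline$women[order(baseline$women$id), ]
  n <- nrow(s)
  d <- tibble(
    overdiagnosed = as.numeric(!is.na(s$dx_age)) - as.numeric(!is.na(b$dx_age)),
    false_positives = as.numeric(s$fp - b$fp),
    deaths_averted = as.numeric(b$bc_death) - as.numeric(s$bc_death),
    lyg = s$py - b$py
  )
  est <- vapply(d, function(v) mean(v) * 1000, numeric(1))
  se <- vapply(d, function(v) stats::sd(v) / sqrt(n) * 1000, numeric(1))
  new_harm_benefit(est, se, meta = list(
    strategy = screened$label, baseline = baseline$label,
    country = screened$country, n_women = n, seed = screened$seed
  ))
}

#' Per-woman overdiagnosis labels (diagnostic)
#'
#' The headline overdiagnosis estimate is the aggregate diagnosed-count
#' difference; this helper additionally labels the individual women
#' diagnosed under screening who are never diagnosed in their baseline
#' lifetime.
#'
#' @param screened,baseline Paired `scenario_outcome` objects.
#' @return Tibble with `id` and logical `overdiagnosed`.
#' @export
overdiagnosis_labels <- function(screened, baseline) {
  check_paired(screened, baseline)
  s <- screened$women[order(screened$women$id), ]
  b <- baseline$women[order(baseline$women$id), ]
  tibble(id = s$id, overdiagnosed = !is.na(s$dx_age) & is.na(b$dx_age))
}

#' @export
tidy.harm_benefit <- function(x, ...) {
  tibble(
    quantity = names(attr(x, "se")),
    per_1000 = unlist(x[1, ], use.names = FALSE),
    se = unname(attr(x, "se"))
  )
}

#' The four harm-to-benefit ratios
#'
#' Overdiagnosed cases and false positives, each divided by breast-cancer
#' deaths averted and by life-years gained. Values are unrounded; use
#' [round_ratio_set()] for presentation at the customary precision.
#'
#' @param hb A `harm_benefit` row (or anything with the four fields).
#' @return A `ratio_set` one-row tibble with `od_per_da`, `fp_per_da`,
#'   `od_per_lyg`, `fp_per_lyg`.
#' @export
ratios <- function(hb) {
  da <- hb[["deaths_averted"]]
  lyg <- hb[["lyg"]]
  if (!isTRUE(da > 0) || !isTRUE(lyg > 0)) {
    abort("harm-to-benefit ratios are undefined: deaths averted and LYG must be > 0",
          class = "screensim_undefined_ratio")
  }
  out <- tibble(
    od_per_da = hb[["overdiagnosed"]] / da,
    fp_per_da = hb[["false_positives"]] / da,
    od_per_lyg = hb[["overdiagnosed"]] / lyg,
    fp_per_lyg = hb[["false_positives"]] / lyg
  )
  structure(out, class = c("ratio_set", class(out)))
}

#' Round half away from zero
#'
#' Presentation rounding used for the outcome tables (base R's `round()`
#' rounds half to even, which does not reproduce the published cells).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round a ratio set to table precision
#'
#' One decimal for the per-death-averted and false-positive ratios, three
#' decimals for overdiagnoses per life-year gained (whose magnitude is
#' hundredths), rounding half away from zero.
#'
#' @param rs A `ratio_set`.
#' @return A one-row tibble of rounded ratios.
#' @export
round_ratio_set <- function(rs) {
  tibble(
    od_per_da = round_half_away(rs[["od_per_da"]], 1),
    fp_per_da = round_half_away(rs[["fp_per_da"]], 1),
    od_per_lyg = round_half_away(rs[["od_per_lyg"]], 3),
    fp_per_lyg = round_half_away(rs[["fp_per_lyg"]], 1)
  )
}

#' Cumulative harms and benefits from a reference plus an increment
#'
#' Outcome tables print a reference strategy's absolute harms/benefits and
#' "+" increments for the alternatives; componentwise addition recovers the
#' alternative's absolute (cumulative) values, whose [ratios()] are the
#' table's printed ratio cells.
#'
#' @param reference,increment `harm_benefit` rows (same per-1000 scale).
#' @return A `harm_benefit` row with summed components.
#' @export
cumulative_hb <- function(reference, increment) {
  est <- c(
    overdiagnosed = reference[["overdiagnosed"]] + increment[["overdiagnosed"]],
    false_positives = reference[["false_positives"]] + increment[["false_positives"]],
    deaths_averted = reference[["deaths_averted"]] + increment[["deaths_averted"]],
    lyg = reference[["lyg"]] + increment[["lyg"]]
  )
  se_r <- attr(reference, "se")
  se_i <- attr(increment, "se")
  se <- if (!is.null(se_r) && !is.null(se_i)) sqrt(se_r^2 + se_i^2) else
    stats::setNames(rep(NA_real_, 4), names(est))
  new_harm_benefit(est, se)
}

#' Percent change in harm-to-benefit ratios versus a reference
#'
#' @param alt,ref `ratio_set` rows; all reference ratios must be nonzero.
#' @return One-row tibble of signed percentages, `100 * (alt - ref) / ref`.
#' @export
percent_change <- function(alt, ref) {
  cols <- c("od_per_da", "fp_per_da", "od_per_lyg", "fp_per_lyg")
  refv <- unlist(ref[1, cols])
  if (any(refv == 0)) {
    abort("percent change undefined: a reference ratio is zero",
          class = "screensim_undefined_ratio")
  }
  altv <- unlist(alt[1, cols])
  out <- as_tibble(as.list(100 * (altv - refv) / refv))
  names(out) <- cols
  out
}
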