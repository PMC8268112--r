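# Reflect arbitrary reals into [0, 1] (fold at the bounds) so an
# unconstrained simplex search respects the probability bounds.
fold01 <- function(x) {
  z <- abs(x) %% 2
  pmin(z, 2 - z)
}

#' Detection-rate observables of one screening overlay
#'
#' The observables the calibration matches: screen detections per 1000
#' screens, by stage at detection, plus the overall rates at first and at
#' subsequent attended rounds.
#'
#' @param arm Per-woman tibble from [run_screening_arm()].
#' @param schedule_start First possible screening age (detections at that
#'   age count as first-round).
#' @return Tibble with `quantity` and `value`.
#' @export
detection_observables <- function(arm, schedule_start) {
  obs_from_events(sum(arm$screens), match(arm$screen_dx_stage, STAGES),
                  arm$screen_dx_age, schedule_start)
}

obs_from_events <- function(total_screens, det_stage_idx, det_age, schedule_start) {
  if (total_screens == 0) abort("no screens performed", class = "screensim_bad_params")
  per_stage <- tabulate(det_stage_idx, nbins = 5L) / total_screens * 1000
  first <- !is.na(det_age) & det_age <= schedule_start + 1
  later <- !is.na(det_age) & !first
  tibble(
    quantity = c(paste0("det_rate_", STAGES), "det_rate_first_round",
                 "det_rate_subsequent_rounds"),
    value = c(per_stage, sum(first) / total_screens * 1000,
              sum(later) / total_screens * 1000)
  )
}

#' Generate calibration targets from the simulator
#'
#' Runs the screening overlay at the bundle's own sensitivities and returns
#' the detection-rate observables as a target table (used for
#' self-consistency and parameter-recovery exercises; real targets would
#' come from registry data via [read_calibration_targets()]).
#'
#' @param params A [country_params()] bundle.
#' @param strategy A [strategy()] or label.
#' @param n_women,seed Simulation size and master seed.
#' @param quantities Which observables to keep (default: the five per-stage
#'   detection rates plus the overall first-round and subsequent-round
#'   rates; the round-type split is what separates sensitivity from the
#'   prevalent pool carried between rounds).
#' @return Tibble with `quantity`, `observed_value`, `weight`.
#' @export
make_calibration_targets <- function(params, strategy = "50-69", n_women, seed,
                                     quantities = c(paste0("det_rate_", STAGES),
                                                    "det_rate_first_round",
                                                    "det_rate_subsequent_rounds")) {
  if (is.character(strategy)) strategy <- parse_strategy_label(strategy)
  histories <- sample_histories(params, n_women, seed)
  arm <- run_screening_arm(histories, strategy)
  obs <- detection_observables(arm, strategy$start_age)
  obs |>
    filter(.data$quantity %in% quantities) |>
    transmute(quantity = .data$quantity, observed_value = .data$value, weight = 1)
}

#' Read calibration targets from CSV
#'
#' @param path CSV with columns `quantity`, `observed_value` and optional
#'   `weight` (default 1).
#' @return Target tibble.
#' @export
read_calibration_targets <- function(path) {
  t <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("quantity", "observed_value") %in% names(t))) {
    abort("targets need columns `quantity` and `observed_value`",
          class = "screensim_bad_params")
  }
  if (!"weight" %in% names(t)) t$weight <- 1
  t
}

#' Calibrate stage-specific screening sensitivities
#'
#' Fits the free sensitivities by derivative-free minimization (Nelder-Mead
#' simplex with reflection of iterates into \[0, 1\]) of the weighted sum of
#' squared relative deviations between simulated and target detection-rate
#' observables. Life histories are generated once from the master seed and
#' reused for every objective evaluation (common random numbers), so the
#' objective is an exactly deterministic function of the parameters and the
#' whole calibration is reproducible.
#'
#' @param params A [country_params()] bundle (its sensitivities seed the
#'   fixed values of non-free stages).
#' @param targets Tibble with `quantity`, `observed_value` (> 0), `weight`.
#' @param strategy Strategy under which the targets were observed.
#' @param n_women Women per objective evaluation.
#' @param budget Maximum objective evaluations (>= 1).
#' @param seed Master seed for the common-random-numbers cohort.
#' @param free Names of the stages whose sensitivity is fitted.
#' @param start Starting values for the free sensitivities.
#' @return A `calibration_result`: `fitted` (named sensitivities in
#'   \[0, 1\]), `objective_value`, `evaluations`, `converged`.
#' @export
calibrate_sensitivities <- function(params, targets, strategy = "50-69",
                                    n_women = 1e5, budget = 500, seed = 1,
                                    free = STAGES,
                                    start = rep(0.7, length(free))) {
  if (!is.numeric(budget) || budget < 1) {
    abort("`budget` must be >= 1 objective evaluations", class = "screensim_bad_params")
  }
  if (!all(free %in% STAGES)) {
    abort("`free` must name preclinical stages", class = "screensim_bad_params")
  }
  if (nrow(targets) < length(free)) {
    abort(paste0("unidentifiable setup: ", nrow(targets), " target(s) for ",
                 length(free), " free parameter(s)"),
          class = "screensim_unidentifiable")
  }
  if (any(targets$observed_value <= 0)) {
    abort("target observed values must be positive (relative deviations)",
          class = "screensim_bad_params")
  }
  if (is.character(strategy)) strategy <- parse_strategy_label(strategy)

  histories <- sample_histories(params, n_women, seed)
  base_sens <- params$policy$sensitivity
  referral <- params$policy$referral
  weights <- targets$weight %||% rep(1, nrow(targets))

  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  objective <- function(theta) {
    counter$n <- counter$n + 1L
    sens <- base_sens
    sens[free] <- fold01(theta)
    rounds <- screening_rounds(histories, strategy,
                               test = screening_test(sens, referral),
                               coverage = params$policy$coverage)
    obs <- obs_from_events(sum(rounds$screens), rounds$det_stage_idx,
                           rounds$det_age, strategy$start_age)
    sim <- obs$value[match(targets$quantity, obs$quantity)]
    if (anyNA(sim)) {
      abort("unknown target quantity", class = "screensim_bad_params")
    }
    sum(weights * ((sim - targets$observed_value) / targets$observed_value)^2)
  }

  if (budget < length(free) + 2) {
    # Too few evaluations for a simplex: score the start only.
    val <- objective(start)
    fit <- stats::setNames(fold01(start), free)
    res <- list(par = start, value = val, convergence = 1L)
  } else {
    # Alternate restarted Nelder-Mead with cyclic coordinate refinement.
    # A single simplex run stalls on the small plateaus of a counting
    # objective; coordinate sweeps (golden-section per sensitivity) fix
    # axis-aligned error, and a fresh simplex then handles the diagonal
    # valleys coordinate descent cannot cross. The objective is exactly
    # deterministic (common random numbers), so the loop is reproducible.
    par <- fold01(start)
    value <- objective(par)
    converged <- FALSE
    repeat {
      prev_cycle <- value
      remaining <- budget - counter$n
      if (remaining < length(free) + 2) break
      maxit <- max(length(free) + 2, min(200, floor(remaining / 2)))
      res <- stats::optim(par, objective, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-10))
      if (res$value < value) {
        par <- fold01(res$par)
        value <- res$value
      }
      repeat {
        improved <- FALSE
        for (k in seq_along(par)) {
          if (budget - counter$n < 25) break
          opt <- stats::optimize(function(z) {
            th <- par
            th[k] <- z
            objective(th)
          }, interval = c(0, 1), tol = 1e-3)
          if (opt$objective < value - 1e-12) {
            par[k] <- opt$minimum
            value <- opt$objective
            improved <- TRUE
          }
        }
        if (!improved || budget - counter$n < 25) break
      }
      if (value < 1e-12) {
        converged <- TRUE
        break
      }
      if (prev_cycle - value <= 1e-10 * max(1, prev_cycle)) {
        converged <- TRUE # no cycle-to-cycle improvement: local optimum
        break
      }
    }
    res <- list(par = par, value = value,
                convergence = if (converged) 0L else 1L)
    fit <- stats::setNames(fold01(par), free)
  }
  structure(
    list(fitted = fit, objective_value = res$value,
         evaluations = counter$n, converged = res$convergence == 0L,
         free = free, n_women = n_women, seed = seed),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> objective ", format(x$objective_value, digits = 4),
      " after ", x$evaluations, " evaluations",
      if (x$converged) " (converged)" else " (budget reached)", "\n", sep = "")
  print(round(x$fitted, 4))
  invisible(x)
}

#' @export
tidy.calibration_result <- function(x, ...) {
  tibble(stage = names(x$fitted), sensitivity = unname(x$fitted))
}

#' @export
glance.calibration_result <- function(x, ...) {
  tibble(objective_value = x$objective_value, evaluations = x$evaluations,
         converged = x$converged, n_women = x$n_women, seed = x$seed)
}
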