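#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Preclinical stage sequence: ductal carcinoma in situ, then invasive tumour
# size classes. Progression is strictly along this order.
STAGES <- c("DCIS", "T1a", "T1b", "T1c", "T2plus")

# Five-year age groups used for examination coverage (screening ages 45-74).
COVERAGE_GROUPS <- c("45-49", "50-54", "55-59", "60-64", "65-69", "70-74")

# Age groups at diagnosis used for the cure-probability table.
CURE_AGE_GROUPS <- c("45-49", "50-59", "60-69", "70plus")

# Reserved per-woman uniform draws for screening rounds (enough for the
# longest strategy, 45-74 biennial = 15 rounds).
MAX_ROUNDS <- 16L

stage_index <- function(stage) match(stage, STAGES)

coverage_group_index <- function(age) {
  idx <- findInterval(age, c(45, 50, 55, 60, 65, 70, 75))
  idx[age >= 75] <- 6L # clamp: no screening is scheduled beyond 74 anyway
  idx
}

cure_age_group_index <- function(age) {
  findInterval(age, c(0, 50, 60, 70, Inf))
}

#' Validate a life table
#'
#' A life table is a tibble with integer column `age` (contiguous,
#' ascending) and column `q`, the annual probability of death from causes
#' other than breast cancer. The terminal row must have `q = 1` so that
#' every woman dies by the end of the table.
#'
#' @param life_table A data frame with columns `age` and `q`.
#' @return The validated life table, invisibly coerced to a tibble.
#' @export
validate_life_table <- function(life_table) {
  lt <- as_tibble(life_table)
  if (!all(c("age", "q") %in% names(lt))) {
    abort("life table needs columns `age` and `q`", class = "screensim_bad_params")
  }
  if (nrow(lt) < 1L || any(diff(lt$age) != 1L)) {
    abort("life-table ages must be contiguous ascending integers",
          class = "screensim_bad_params")
  }
  if (any(!is.finite(lt$q)) || any(lt$q < 0 | lt$q > 1)) {
    abort("life-table `q` must lie in [0, 1]", class = "screensim_bad_params")
  }
  if (lt$q[nrow(lt)] != 1) {
    abort("terminal life-table `q` must equal 1", class = "screensim_bad_params")
  }
  invisible(lt)
}

validate_onset <- function(onset) {
  on <- as_tibble(onset)
  if (!all(c("age", "lambda") %in% names(on))) {
    abort("onset model needs columns `age` and `lambda`", class = "screensim_bad_params")
  }
  if (any(diff(on$age) != 1L)) {
    abort("onset ages must be contiguous ascending integers", class = "screensim_bad_params")
  }
  if (any(!is.finite(on$lambda)) || any(on$lambda < 0)) {
    abort("onset hazard must be finite and non-negative", class = "screensim_bad_params")
  }
  invisible(on)
}

validate_natural_history <- function(nh) {
  p <- nh$p_nonprogressive_dcis
  if (is.null(p) || p < 0 || p > 1) {
    abort("p_nonprogressive_dcis must lie in [0, 1]", class = "screensim_bad_params")
  }
  for (field in c("dwell_rates", "clinical_hazards")) {
    v <- nh[[field]]
    if (is.null(v) || !all(STAGES %in% names(v)) || any(v[STAGES] < 0)) {
      abort(paste0("`", field, "` must be a non-negative vector named by stage"),
            class = "screensim_bad_params")
    }
  }
  invisible(nh)
}

validate_survival <- function(sv) {
  cure <- sv$cure
  if (is.null(cure) || !is.matrix(cure) ||
      !identical(rownames(cure), STAGES) ||
      !identical(colnames(cure), CURE_AGE_GROUPS)) {
    abort("`cure` must be a stage x age-group matrix (rows DCIS..T2plus)",
          class = "screensim_bad_params")
  }
  if (any(cure < 0 | cure > 1)) {
    abort("cure probabilities must lie in [0, 1]", class = "screensim_bad_params")
  }
  if (is.null(sv$ttd_mean) || !all(STAGES %in% names(sv$ttd_mean)) ||
      any(sv$ttd_mean[STAGES] <= 0)) {
    abort("`ttd_mean` (mean years from diagnosis to breast-cancer death) must be positive per stage",
          class = "screensim_bad_params")
  }
  if (is.null(sv$screen_benefit) || sv$screen_benefit < 1) {
    abort("`screen_benefit` must be >= 1", class = "screensim_bad_params")
  }
  invisible(sv)
}

validate_policy <- function(policy) {
  s <- policy$sensitivity
  if (is.null(s) || !all(STAGES %in% names(s)) || any(s[STAGES] < 0 | s[STAGES] > 1)) {
    abort("`sensitivity` must lie in [0, 1] per stage", class = "screensim_bad_params")
  }
  r <- policy$referral
  if (is.null(r) || !all(c("under50", "over50") %in% names(r)) || any(r < 0 | r > 1)) {
    abort("`referral` must have under50/over50 probabilities in [0, 1]",
          class = "screensim_bad_params")
  }
  cov <- policy$coverage
  if (is.null(cov) || length(cov) != length(COVERAGE_GROUPS) ||
      any(cov < 0 | cov > 1)) {
    abort("`coverage` must give one probability per 5-year age group 45-49..70-74",
          class = "screensim_bad_params")
  }
  invisible(policy)
}

#' Bundle country parameters
#'
#' Assembles (and validates) the full parameter bundle driving one
#' country's simulation: life table, age-specific preclinical onset
#' hazard, natural-history parameters, survival model and screening
#' policy parameters.
#'
#' @param name Country label.
#' @param life_table Tibble with `age`, `q` (other-cause death probability).
#' @param onset Tibble with `age`, `lambda` (preclinical DCIS onset hazard
#'   per woman-year).
#' @param natural_history List with `p_nonprogressive_dcis`, `dwell_rates`
#'   and `clinical_hazards` (both named by stage, per year).
#' @param survival List with `cure` (stage x age-group matrix of cure
#'   probabilities), `ttd_mean` (mean years from diagnosis to breast-cancer
#'   death per stage) and `screen_benefit` (multiplicative cure improvement
#'   on screen detection, clamped at 1).
#' @param policy List with `sensitivity` (per stage), `referral`
#'   (`under50`/`over50`), `coverage` (per 5-year age group; all 1 for the
#'   100%-attendance analyses) and optionally `observed_coverage`.
#' @return A `country_params` object.
#' @export
country_params <- function(name, life_table, onset, natural_history,
                           survival, policy) {
  lt <- validate_life_table(life_table)
  on <- validate_onset(onset)
  validate_natural_history(natural_history)
  validate_survival(survival)
  validate_policy(policy)
  structure(
    list(name = name, life_table = lt, onset = on,
         natural_history = natural_history, survival = survival,
         policy = policy),
    class = "country_params"
  )
}

#' @export
print.country_params <- function(x, ...) {
  cat("<country_params> ", x$name, "\n", sep = "")
  cat("  life table ages ", min(x$life_table$age), "-", max(x$life_table$age), "\n", sep = "")
  cat("  p(non-progressive DCIS) = ", x$natural_history$p_nonprogressive_dcis, "\n", sep = "")
  cat("  sensitivity: ",
      paste(sprintf("%s=%.3g", STAGES, x$policy$sensitivity[STAGES]), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
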