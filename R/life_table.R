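#' Build a Gompertz life table
#'
#' Annual other-cause death probabilities follow a Gompertz hazard:
#' `q(age) = 1 - exp(-a * exp(b * (age - start_age)))`, clamped to 1 at the
#' terminal age so the cohort is extinct by the table's end.
#'
#' @param a Baseline annual hazard at `start_age` (must be positive).
#' @param b Log-hazard slope per year of age (non-negative).
#' @param start_age,terminal_age Integer bounds of the table (default 45-100).
#' @return A life-table tibble with columns `age` and `q`.
#' @examples
#' lt <- make_life_table(0.005, 0.09)
#' life_expectancy(lt)
#' @export
make_life_table <- function(a, b, start_age = 45L, terminal_age = 100L) {
  if (!is.finite(a) || a <= 0) {
    abort("Gompertz `a` must be positive", class = "screensim_bad_params")
  }
  if (!is.finite(b) || b < 0) {
    abort("Gompertz `b` must be non-negative", class = "screensim_bad_params")
  }
  ages <- seq.int(start_age, terminal_age)
  q <- 1 - exp(-a * exp(b * (ages - start_age)))
  q[length(q)] <- 1
  tibble(age = ages, q = q)
}

# Cohort survival to the start of each year of age (S[1] = 1).
lt_survival <- function(life_table) {
  cumprod(c(1, 1 - life_table$q[-nrow(life_table)]))
}

#' Expected age at death from a life table
#'
#' Deterministic life expectancy by direct summation, under the same
#' within-year-uniform death-time convention the simulator uses: a woman
#' dying in year `age` dies on average at `age + 0.5`.
#'
#' @param life_table A valid life table.
#' @return Expected age at death (years).
#' @export
life_expectancy <- function(life_table) {
  lt <- validate_life_table(life_table)
  S <- lt_survival(lt)
  p_die <- S * lt$q
  sum(p_die * (lt$age + 0.5))
}

#' Sample ages at death from other causes
#'
#' Inverts the life table's annual death probabilities: the year of death is
#' drawn from the exact cohort distribution and the death time is uniform
#' within that year. One uniform draw per woman drives both.
#'
#' @param life_table A valid life table.
#' @param n Number of draws (ignored when `u` is supplied).
#' @param u Optional vector of uniforms in \[0, 1) to invert; when `NULL`,
#'   `n` fresh uniforms are drawn from the current RNG stream.
#' @return Continuous ages at death, all in `[min(age), max(age) + 1)`.
#' @export
sample_other_cause_death <- function(life_table, n = length(u), u = NULL) {
  lt <- validate_life_table(life_table)
  if (is.null(u)) u <- stats::runif(n)
  S <- lt_survival(lt)
  p_die <- S * lt$q
  cum <- cumsum(p_die) # last element is 1 (terminal q = 1)
  yr <- findInterval(u, cum, left.open = TRUE) + 1L
  yr <- pmin(yr, nrow(lt))
  lo <- c(0, cum)[yr]
  frac <- (u - lo) / p_die[yr]
  frac[!is.finite(frac)] <- 0
  lt$age[yr] + pmin(pmax(frac, 0), 1 - 1e-12)
}
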