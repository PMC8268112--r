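# Published screening-policy parameters for the four exemplary national
# programmes (observed examination coverage by 5-year age group, calibrated
# stage-specific digital-mammography sensitivities, and observed referral
# rates by age band). These are real inputs; everything natural-history in
# the fixtures below is SYNTHETIC.

COUNTRY_NAMES <- c("slovenia", "finland", "netherlands", "italy")

POLICY_TABLE <- list(
  slovenia = list(
    coverage = c(0.543, 0.543, 0.650, 0.524, 0.488, 0.488),
    sensitivity = c(DCIS = 0.726, T1a = 0.785, T1b = 0.656, T1c = 0.780, T2plus = 1),
    referral = c(under50 = 0.040, over50 = 0.034)
  ),
  finland = list(
    coverage = c(0.850, 0.850, 0.859, 0.868, 0.730, 0.730),
    sensitivity = c(DCIS = 0.596, T1a = 0.811, T1b = 0.761, T1c = 0.946, T2plus = 1),
    referral = c(under50 = 0.030, over50 = 0.028)
  ),
  netherlands = list(
    coverage = c(0.755, 0.755, 0.762, 0.763, 0.757, 0.701),
    sensitivity = c(DCIS = 0.865, T1a = 0.553, T1b = 0.481, T1c = 0.857, T2plus = 1),
    referral = c(under50 = 0.030, over50 = 0.023)
  ),
  italy = list(
    coverage = c(0.596, 0.596, 0.632, 0.639, 0.615, 0.615),
    sensitivity = c(DCIS = 0.821, T1a = 1, T1b = 0.717, T1c = 0.814, T2plus = 1),
    referral = c(under50 = 0.065, over50 = 0.058)
  )
)

# SYNTHETIC natural-history structure shared by the four fixtures; the
# calibrated national values are not public, so these are chosen once to
# give outcomes of the right order of magnitude (single-digit overdiagnoses
# and deaths averted, hundreds of false positives and life-years gained per
# 1000 women) and to preserve the published benefit ordering across
# countries via the onset level. They are not estimates of any country.
SYNTH_NH <- list(
  p_nonprogressive_dcis = 0.03,
  dwell_rates = c(DCIS = 0.50, T1a = 1.00, T1b = 0.80, T1c = 0.60, T2plus = 0),
  clinical_hazards = c(DCIS = 0.03, T1a = 0.10, T1b = 0.25, T1c = 0.55, T2plus = 1.20)
)

SYNTH_CURE <- matrix(
  c(0.97, 0.96, 0.95, 0.94,
    0.92, 0.91, 0.90, 0.88,
    0.86, 0.85, 0.83, 0.80,
    0.70, 0.68, 0.66, 0.62,
    0.40, 0.38, 0.36, 0.32),
  nrow = 5, byrow = TRUE,
  dimnames = list(c("DCIS", "T1a", "T1b", "T1c", "T2plus"),
                  c("45-49", "50-59", "60-69", "70plus"))
)

SYNTH_SURVIVAL <- list(
  cure = SYNTH_CURE,
  ttd_mean = c(DCIS = 12, T1a = 10, T1b = 8, T1c = 6, T2plus = 4),
  screen_benefit = 1.2
)

# Country-level SYNTHETIC demography and disease-risk scaling: Gompertz
# other-cause mortality and the plateau of the logistic onset hazard. The
# onset ordering (Netherlands highest, Slovenia lowest) preserves the
# published ordering of screening benefit across the four programmes.
SYNTH_COUNTRY <- list(
  slovenia = list(gompertz = c(a = 0.0014, b = 0.105), onset_plateau = 0.0026),
  finland = list(gompertz = c(a = 0.0013, b = 0.105), onset_plateau = 0.0028),
  netherlands = list(gompertz = c(a = 0.00125, b = 0.105), onset_plateau = 0.0048),
  italy = list(gompertz = c(a = 0.0012, b = 0.105), onset_plateau = 0.0040)
)

#' Logistic age-specific onset hazard
#'
#' Annual hazard of preclinical DCIS onset rising smoothly to a plateau:
#' `lambda(age) = plateau / (1 + exp(-slope * (age - midpoint)))`, defined
#' from age 20.
#'
#' @param plateau Asymptotic hazard per woman-year.
#' @param midpoint Age of half-plateau (default 52).
#' @param slope Logistic steepness per year (default 0.15).
#' @param ages Integer age grid (default 20-100).
#' @return Tibble with `age` and `lambda`.
#' @export
make_onset_curve <- function(plateau, midpoint = 52, slope = 0.15, ages = 20:100) {
  if (plateau < 0) abort("plateau must be >= 0", class = "screensim_bad_params")
  tibble(age = as.integer(ages),
         lambda = plateau / (1 + exp(-slope * (ages - midpoint))))
}

#' Specification of a synthetic country fixture
#'
#' Collects every number needed to generate a complete, internally
#' consistent [country_params()] bundle.
#'
#' @param gompertz Named vector `c(a=, b=)` for the other-cause life table.
#' @param onset_plateau,onset_midpoint,onset_slope Logistic onset hazard.
#' @param natural_history,survival Optional overrides of the shared
#'   synthetic defaults.
#' @param sensitivity,referral,coverage Screening-policy parameters;
#'   `coverage` is the observed per-age-group attendance (stored as
#'   `observed_coverage`; the working coverage defaults to 100%).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(gompertz, onset_plateau, onset_midpoint = 52,
                         onset_slope = 0.15, natural_history = SYNTH_NH,
                         survival = SYNTH_SURVIVAL,
                         sensitivity, referral,
                         coverage = rep(1, length(COVERAGE_GROUPS))) {
  structure(
    list(gompertz = gompertz, onset_plateau = onset_plateau,
         onset_midpoint = onset_midpoint, onset_slope = onset_slope,
         natural_history = natural_history, survival = survival,
         sensitivity = sensitivity, referral = referral, coverage = coverage),
    class = "fixture_spec"
  )
}

#' Build country parameters from a fixture specification
#'
#' @param spec A [fixture_spec()].
#' @param name Country label.
#' @return A [country_params()] bundle with 100% working coverage and the
#'   observed coverage stored for the sensitivity-analysis variant.
#' @export
build_country_params <- function(spec, name) {
  params <- country_params(
    name = name,
    life_table = make_life_table(spec$gompertz[["a"]], spec$gompertz[["b"]]),
    onset = make_onset_curve(spec$onset_plateau, spec$onset_midpoint, spec$onset_slope),
    natural_history = spec$natural_history,
    survival = spec$survival,
    policy = list(
      sensitivity = spec$sensitivity,
      referral = spec$referral,
      coverage = rep(1, length(COVERAGE_GROUPS)),
      observed_coverage = spec$coverage
    )
  )
  params
}

#' Synthetic country fixture
#'
#' Returns a complete parameter bundle for one of the four exemplary
#' countries: the published policy parameters (stage-specific sensitivity,
#' referral rates by age band, observed examination coverage — with ages
#' 45-49 and 70-74 reusing the nearest observed group where the programme
#' screened 50-69) combined with SYNTHETIC natural-history, survival and
#' demography defaults. Working coverage is 100%, matching the base
#' analyses; the observed coverage drives the `observed_coverage` variant.
#'
#' @param name One of `"slovenia"`, `"finland"`, `"netherlands"`, `"italy"`.
#' @return A [country_params()] bundle.
#' @examples
#' country_fixture("finland")$policy$sensitivity[["T1c"]] # 0.946
#' @export
country_fixture <- function(name) {
  name <- tolower(name)
  if (!name %in% COUNTRY_NAMES) {
    abort(paste0("unknown country '", name, "'; expected one of ",
                 paste(COUNTRY_NAMES, collapse = ", ")),
          class = "screensim_bad_params")
  }
  pol <- POLICY_TABLE[[name]]
  syn <- SYNTH_COUNTRY[[name]]
  build_country_params(
    fixture_spec(gompertz = syn$gompertz, onset_plateau = syn$onset_plateau,
                 sensitivity = pol$sensitivity, referral = pol$referral,
                 coverage = pol$coverage),
    name = name
  )
}

#' Sensitivity-analysis parameter variants
#'
#' Applies one of the cross-country sensitivity-analysis variants to a
#' parameter bundle: the per-stage lowest/highest calibrated sensitivities
#' across the four programmes, the lowest/highest observed referral rates
#' (Netherlands and Italy respectively), or the observed examination
#' coverage in place of 100%. Applying a variant twice equals applying it
#' once.
#'
#' @param params A [country_params()] bundle.
#' @param variant One of `"base"`, `"lowest_sensitivity"`,
#'   `"highest_sensitivity"`, `"lowest_referral"`, `"highest_referral"`,
#'   `"observed_coverage"`.
#' @return The modified bundle.
#' @export
variant_params <- function(params, variant) {
  variants <- c("base", "lowest_sensitivity", "highest_sensitivity",
                "lowest_referral", "highest_referral", "observed_coverage")
  if (!variant %in% variants) {
    abort(paste0("unknown variant '", variant, "'"), class = "screensim_bad_params")
  }
  sens_all <- do.call(rbind, lapply(POLICY_TABLE, `[[`, "sensitivity"))
  ref_all <- do.call(rbind, lapply(POLICY_TABLE, `[[`, "referral"))
  pol <- params$policy
  if (variant == "lowest_sensitivity") pol$sensitivity <- apply(sens_all, 2, min)
  if (variant == "highest_sensitivity") pol$sensitivity <- apply(sens_all, 2, max)
  if (variant == "lowest_referral") pol$referral <- ref_all["netherlands", ]
  if (variant == "highest_referral") pol$referral <- ref_all["italy", ]
  if (variant == "observed_coverage") {
    if (is.null(pol$observed_coverage)) {
      abort("bundle carries no observed coverage", class = "screensim_bad_params")
    }
    pol$coverage <- pol$observed_coverage
  }
  params$policy <- pol
  params
}

#' Write country parameters as a YAML config
#'
#' The file carries a header marking the natural-history content as
#' synthetic. Writing is deterministic: identical bundles give
#' byte-identical files.
#'
#' @param params A [country_params()] bundle.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_country_params <- function(params, path) {
  x <- list(
    name = params$name,
    life_table = list(age = params$life_table$age, q = params$life_table$q),
    onset = list(age = params$onset$age, lambda = params$onset$lambda),
    natural_history = list(
      p_nonprogressive_dcis = params$natural_history$p_nonprogressive_dcis,
      dwell_rates = as.list(params$natural_history$dwell_rates[STAGES]),
      clinical_hazards = as.list(params$natural_history$clinical_hazards[STAGES])
    ),
    survival = list(
      cure = apply(params$survival$cure, 1, as.list, simplify = FALSE),
      ttd_mean = as.list(params$survival$ttd_mean[STAGES]),
      screen_benefit = params$survival$screen_benefit
    ),
    policy = list(
      sensitivity = as.list(params$policy$sensitivity[STAGES]),
      referral = as.list(params$policy$referral),
      coverage = params$policy$coverage,
      observed_coverage = params$policy$observed_coverage
    )
  )
  header <- c(
    "# screensim country parameter bundle.",
    "# Policy parameters (sensitivity, referral, observed coverage) are published",
    "# programme values; natural-history, survival and demography parameters are",
    "# SYNTHETIC stand-ins, not calibrated national estimates.",
    ""
  )
  writeLines(c(header, yaml::as.yaml(x, precision = 15)), path)
  invisible(path)
}

#' Read country parameters from a YAML config
#'
#' @param path File written by [write_country_params()] (or hand-edited in
#'   the same schema).
#' @return A validated [country_params()] bundle.
#' @export
read_country_params <- function(path) {
  x <- yaml::read_yaml(path)
  cure <- do.call(rbind, lapply(x$survival$cure, function(row) unlist(row)[CURE_AGE_GROUPS]))
  rownames(cure) <- STAGES
  pol <- list(
    sensitivity = unlist(x$policy$sensitivity)[STAGES],
    referral = unlist(x$policy$referral)[c("under50", "over50")],
    coverage = as.numeric(x$policy$coverage),
    observed_coverage = if (!is.null(x$policy$observed_coverage))
      as.numeric(x$policy$observed_coverage)
  )
  country_params(
    name = x$name,
    life_table = tibble(age = as.integer(x$life_table$age), q = as.numeric(x$life_table$q)),
    onset = tibble(age = as.integer(x$onset$age), lambda = as.numeric(x$onset$lambda)),
    natural_history = list(
      p_nonprogressive_dcis = x$natural_history$p_nonprogressive_dcis,
      dwell_rates = unlist(x$natural_history$dwell_rates)[STAGES],
      clinical_hazards = unlist(x$natural_history$clinical_hazards)[STAGES]
    ),
    survival = list(
      cure = cure,
      ttd_mean = unlist(x$survival$ttd_mean)[STAGES],
      screen_benefit = x$survival$screen_benefit
    ),
    policy = pol
  )
}

#' Published per-1000 screening outcomes for four European programmes
#'
#' The published microsimulation estimates this package's outcome
#' arithmetic is validated against: per 1000 women aged 45 followed for
#' life, the number of screens, harms (overdiagnosed cases, false
#' positives) and benefits (breast-cancer deaths averted, life-years
#' gained) of four biennial strategies, plus the printed harm-to-benefit
#' ratio cells. The reference strategy 50-69 is absolute versus no
#' screening; the alternative rows are increments over the reference.
#'
#' @return A tibble with one row per country x strategy.
#' @export
published_screening_outcomes <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~country, ~strategy, ~reference, ~screens, ~overdiagnosed, ~false_positives,
    ~deaths_averted, ~lyg, ~od_per_da, ~fp_per_da, ~od_per_lyg, ~fp_per_lyg,
    "slovenia", "50-69", TRUE, 9236, 3.3, 275.8, 7.3, 96.5, 0.5, 37.9, 0.034, 2.9,
    "slovenia", "45-74", FALSE, 13723, 1.8, 220.8, 2.6, 32.7, 0.5, 50.3, 0.040, 3.8,
    "slovenia", "45-69", FALSE, 11696, 0.1, 150.2, 0.8, 18.2, 0.4, 53.0, 0.030, 3.7,
    "slovenia", "50-74", FALSE, 11264, 1.7, 58.4, 1.9, 14.8, 0.5, 36.6, 0.045, 3.0,
    "finland", "50-69", TRUE, 9170, 2.6, 212.3, 7.7, 105.3, 0.3, 27.6, 0.025, 2.0,
    "finland", "45-74", FALSE, 13632, 1.5, 135.6, 3.2, 38.8, 0.4, 31.9, 0.029, 2.4,
    "finland", "45-69", FALSE, 12034, 0.4, 96.7, 1.4, 24.2, 0.3, 34.2, 0.023, 2.4,
    "finland", "50-74", FALSE, 11183, 1.4, 48.8, 2.4, 19.4, 0.4, 25.9, 0.032, 2.1,
    "netherlands", "50-69", TRUE, 8948, 3.2, 150.1, 13.0, 185.6, 0.2, 11.6, 0.017, 0.8,
    "netherlands", "45-74", FALSE, 13288, 1.9, 172.5, 4.2, 59.5, 0.3, 18.8, 0.021, 1.3,
    "netherlands", "45-69", FALSE, 11388, 0.2, 129.7, 1.8, 40.0, 0.2, 19.0, 0.015, 1.2,
    "netherlands", "50-74", FALSE, 10848, 1.7, 29.5, 2.5, 19.6, 0.3, 11.6, 0.024, 0.9,
    "italy", "50-69", TRUE, 9186, 2.5, 488.5, 10.7, 152.1, 0.2, 45.7, 0.016, 3.2,
    "italy", "45-74", FALSE, 13657, 1.5, 338.8, 3.5, 49.2, 0.3, 58.2, 0.020, 4.1,
    "italy", "45-69", FALSE, 11641, 0.1, 219.1, 1.4, 32.0, 0.2, 58.7, 0.014, 3.8,
    "italy", "50-74", FALSE, 11203, 1.4, 105.5, 2.1, 17.2, 0.3, 46.3, 0.023, 3.5
  )
}
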