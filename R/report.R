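#' Run paired scenarios for several strategies on one country
#'
#' Simulates the no-screening arm once and every requested strategy on the
#' same life histories (same master seed), returning the paired
#' harms/benefits of each strategy versus no screening.
#'
#' @param params A [country_params()] bundle.
#' @param strategies Character vector of strategy labels (default the four
#'   standard biennial age ranges).
#' @param n_women,seed Cohort size and master seed.
#' @param reference Label of the reference strategy (default `"50-69"`).
#' @return A `strategy_comparison`: baseline and per-strategy
#'   `scenario_outcome`s, per-strategy `harm_benefit`s versus no screening,
#'   and metadata.
#' @export
analyze_strategies <- function(params, strategies = c("50-69", "45-74", "45-69", "50-74"),
                               n_women, seed, reference = strategies[[1]]) {
  if (!reference %in% strategies) {
    abort("`reference` must be one of `strategies`", class = "screensim_bad_params")
  }
  histories <- sample_histories(params, n_women, seed)
  baseline <- scenario_from_histories(histories, NULL)
  scenarios <- lapply(strategies, function(lab) {
    scenario_from_histories(histories, parse_strategy_label(lab))
  })
  names(scenarios) <- strategies
  hb <- lapply(scenarios, harms_benefits, baseline = baseline)
  structure(
    list(baseline = baseline, scenarios = scenarios, hb = hb,
         reference = reference, country = params$name,
         n_women = as.integer(n_women), seed = as.integer(seed),
         checksum = digest::digest(params)),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison> country ", x$country, ", n = ", x$n_women,
      ", seed ", x$seed, ", reference ", x$reference, "\n", sep = "")
  print(build_outcome_table(x))
  invisible(x)
}

#' Outcome table in the published layout
#'
#' One row per strategy: absolute screens per 1000 women; harms and
#' benefits absolute for the reference strategy and incremental (`+`) for
#' the alternatives; the four harm-to-benefit ratios computed from each
#' strategy's cumulative values and rounded to table precision.
#'
#' `build_outcome_table()` is generic: give it either a
#' [analyze_strategies()] result, or a data frame of printed columns
#' (`strategy`, `reference`, `overdiagnosed`, `false_positives`,
#' `deaths_averted`, `lyg`, optionally `screens`) in which the
#' non-reference rows are increments over the single reference row — the
#' layout of [published_screening_outcomes()] — to replay the ratio
#' arithmetic on published numbers.
#'
#' @param x A `strategy_comparison` or a data frame as described.
#' @param ... Unused.
#' @return A tibble in the published column order.
#' @export
build_outcome_table <- function(x, ...) UseMethod("build_outcome_table")

#' @export
build_outcome_table.strategy_comparison <- function(x, ...) {
  ref_hb <- x$hb[[x$reference]]
  rows <- lapply(names(x$scenarios), function(lab) {
    hb <- x$hb[[lab]]
    is_ref <- lab == x$reference
    shown <- if (is_ref) hb else {
      vals <- unlist(hb[1, ]) - unlist(ref_hb[1, ])
      as_tibble(as.list(vals))
    }
    rs <- round_ratio_set(ratios(hb))
    tibble(
      strategy = lab, reference = is_ref,
      screens = scenario_value(x$scenarios[[lab]], "screens"),
      overdiagnosed = shown[["overdiagnosed"]],
      false_positives = shown[["false_positives"]],
      deaths_averted = shown[["deaths_averted"]],
      lyg = shown[["lyg"]]
    ) |> bind_cols(rs)
  })
  bind_rows(rows)
}

#' @export
build_outcome_table.data.frame <- function(x, ...) {
  x <- as_tibble(x)
  req <- c("strategy", "reference", "overdiagnosed", "false_positives",
           "deaths_averted", "lyg")
  if (!all(req %in% names(x))) {
    abort(paste0("need columns ", paste(req, collapse = ", ")),
          class = "screensim_bad_params")
  }
  if (sum(x$reference) != 1L) {
    abort("exactly one reference row required", class = "screensim_bad_params")
  }
  ref <- x[x$reference, ]
  ref_hb <- new_harm_benefit(
    c(overdiagnosed = ref$overdiagnosed, false_positives = ref$false_positives,
      deaths_averted = ref$deaths_averted, lyg = ref$lyg),
    se = stats::setNames(rep(NA_real_, 4),
                         c("overdiagnosed", "false_positives", "deaths_averted", "lyg"))
  )
  rows <- lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    inc_hb <- new_harm_benefit(
      c(overdiagnosed = row$overdiagnosed, false_positives = row$false_positives,
        deaths_averted = row$deaths_averted, lyg = row$lyg),
      se = attr(ref_hb, "se")
    )
    cum <- if (row$reference) ref_hb else cumulative_hb(ref_hb, inc_hb)
    rs <- round_ratio_set(ratios(cum))
    out <- row[intersect(c("country", "strategy", "reference", "screens",
                           "overdiagnosed", "false_positives", "deaths_averted",
                           "lyg"), names(row))]
    bind_cols(out, rs)
  })
  bind_rows(rows)
}

#' Percent change in ratios versus the reference strategy
#'
#' @param x A `strategy_comparison`.
#' @return Tibble with one row per alternative strategy and the signed
#'   percent change of each of the four ratios versus the reference.
#' @export
percent_change_table <- function(x) {
  stopifnot(inherits(x, "strategy_comparison"))
  ref_rs <- ratios(x$hb[[x$reference]])
  alts <- setdiff(names(x$hb), x$reference)
  bind_rows(lapply(alts, function(lab) {
    bind_cols(tibble(strategy = lab), percent_change(ratios(x$hb[[lab]]), ref_rs))
  }))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of percent changes in harm-to-benefit ratios
#'
#' @param object A `strategy_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  pct <- percent_change_table(object) |>
    tidyr::pivot_longer(-"strategy", names_to = "ratio", values_to = "pct_change")
  ggplot2::ggplot(pct, ggplot2::aes(x = .data$ratio, y = .data$pct_change,
                                    fill = .data$strategy)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = "% change vs reference strategy",
      title = paste0("Harm-to-benefit ratios vs ", object$reference,
                     " (", object$country, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Sensitivity-analysis grid of harm-to-benefit ratios
#'
#' Runs every country x strategy x variant cell from the same master seed
#' family and reports the four ratios plus their relative change versus the
#' country's base variant.
#'
#' @param countries Country names or a named list of [country_params()].
#' @param variants Variant names (see [variant_params()]); `"base"` is
#'   always run and used as the comparator.
#' @param strategies Strategy labels.
#' @param n_women,seed Per-run cohort size and master seed.
#' @return Tibble: country, variant, strategy, the four ratios, and
#'   `rel_<ratio>` columns (variant ratio / base ratio).
#' @export
run_sensitivity_scenarios <- function(countries = COUNTRY_NAMES,
                                      variants = c("lowest_sensitivity",
                                                   "highest_sensitivity",
                                                   "lowest_referral",
                                                   "highest_referral",
                                                   "observed_coverage"),
                                      strategies = c("50-69", "45-74", "45-69", "50-74"),
                                      n_women, seed) {
  if (is.character(countries)) {
    countries <- stats::setNames(lapply(countries, country_fixture), countries)
  }
  ratio_cols <- c("od_per_da", "fp_per_da", "od_per_lyg", "fp_per_lyg")
  cells <- list()
  for (cname in names(countries)) {
    for (v in unique(c("base", variants))) {
      pv <- variant_params(countries[[cname]], v)
      comp <- analyze_strategies(pv, strategies, n_women = n_women, seed = seed,
                                 reference = strategies[[1]])
      for (lab in strategies) {
        rs <- ratios(comp$hb[[lab]])
        cells[[length(cells) + 1L]] <- bind_cols(
          tibble(country = cname, variant = v, strategy = lab), rs
        )
      }
    }
  }
  out <- bind_rows(cells)
  base <- out |>
    filter(.data$variant == "base") |>
    select("country", "strategy", dplyr::all_of(ratio_cols)) |>
    rename_with(~ paste0("base_", .x), dplyr::all_of(ratio_cols))
  out <- out |> left_join(base, by = c("country", "strategy"))
  for (rc in ratio_cols) {
    out[[paste0("rel_", rc)]] <- out[[rc]] / out[[paste0("base_", rc)]]
  }
  out |> select(-dplyr::starts_with("base_"))
}

check_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  required <- c("country", "n_women", "seed", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0L) {
    abort(paste0("config missing field(s): ", paste(missing, collapse = ", ")),
          class = "screensim_bad_config")
  }
  config$strategies <- config$strategies %||% c("50-69", "45-74", "45-69", "50-74")
  config$reference <- config$reference %||% config$strategies[[1]]
  config$variant <- config$variant %||% "base"
  config
}

#' Run a full screening analysis from a configuration
#'
#' The command-style entry point: resolves the country parameters (fixture
#' name or YAML path), runs the paired no-screening and strategy arms,
#' and writes an outcome table CSV (published column order) plus a JSON
#' file with unrounded estimates, Monte Carlo standard errors and run
#' metadata (master seed, cohort size, parameter checksum, package
#' version). Reruns with an identical configuration produce identical
#' files.
#'
#' @param config A list or path to a YAML file with fields `country`
#'   (fixture name or params YAML path), `n_women`, `seed`, `out_dir`, and
#'   optional `strategies`, `reference`, `variant`.
#' @return The outcome table, invisibly. Side effect: writes
#'   `outcomes_<country>.csv` and `outcomes_<country>.json` in `out_dir`.
#' @export
run_screening_analysis <- function(config) {
  config <- check_config(config)
  params <- if (file.exists(config$country)) read_country_params(config$country)
            else country_fixture(config$country)
  params <- variant_params(params, config$variant)
  for (lab in config$strategies) parse_strategy_label(lab) # fail fast
  comp <- analyze_strategies(params, config$strategies,
                             n_women = config$n_women, seed = config$seed,
                             reference = config$reference)
  tab <- build_outcome_table(comp)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(config$out_dir, paste0("outcomes_", params$name, ".csv"))
  json_path <- file.path(config$out_dir, paste0("outcomes_", params$name, ".json"))
  readr::write_csv(tab, csv_path)
  payload <- list(
    metadata = list(
      country = params$name, variant = config$variant,
      n_women = comp$n_women, seed = comp$seed,
      fixture_checksum = comp$checksum,
      package_version = as.character(utils::packageVersion("screensim"))
    ),
    baseline = tidy(comp$baseline),
    strategies = lapply(comp$hb, function(hb) {
      list(estimates = as.list(hb[1, ]), se = as.list(attr(hb, "se")),
           ratios = as.list(ratios(hb)[1, ]))
    })
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote ", csv_path, " and ", json_path,
          " (n = ", comp$n_women, ", seed ", comp$seed, ")")
  invisible(tab)
}
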