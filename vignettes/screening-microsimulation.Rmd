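---
title: "Microsimulation of breast cancer screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsimulation of breast cancer screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`screensim` is an individual-level (MISCAN-style) microsimulation of breast
cancer natural history with mammography screening overlaid on the same
simulated lives. A cohort of women is followed from age 45 to death in two
counterfactual arms — with and without a screening programme — and the
incremental outcomes are reported per 1000 women:

* **harms**: overdiagnosed breast cancer cases and false-positive referrals;
* **benefits**: breast cancer deaths averted and life-years gained (LYG);
* the four **harm-to-benefit ratios** formed by dividing each harm by each
  benefit.

Overdiagnosis is defined strictly by lifelong counterfactual follow-up: the
difference in the *total* number of diagnosed breast cancers between the
screening and no-screening arms. No woman-level labelling enters the
estimate (a per-woman diagnostic labelling is available separately via
`overdiagnosis_labels()`).

## Natural history

Each woman's latent disease course is drawn once and shared by both arms:

1. **Other-cause death.** An age at death from causes other than breast
   cancer is drawn from an annual life table (probability `q` per year of
   age, uniform death time within the year, terminal `q = 1` at age 100).
2. **Preclinical onset.** Onset of a preclinical ductal carcinoma in situ
   (DCIS) follows an age-specific hazard defined from age 20. Women with a
   clinical diagnosis before 45 are discarded and redrawn, so the simulated
   cohort is "1000 women aged 45, alive and undiagnosed".
3. **Stage progression.** The preclinical sequence is fixed:
   DCIS → T1a → T1b → T1c → T2+. Within each stage an exponential
   *dwell* (progression) clock competes with an exponential
   *clinical-surfacing* clock, both restarted at stage entry; whichever
   rings first decides whether the tumour progresses or surfaces
   symptomatically. T2+ is terminal: the tumour stays there until it
   surfaces or the woman dies. With probability `p_nonprogressive_dcis` a
   DCIS is non-progressive: it neither progresses nor surfaces, ever, and
   remains screen-detectable — this is the main engine of overdiagnosis.
4. **Survival after diagnosis.** A cure model: with probability
   `cure(stage, age group)` the woman never dies of breast cancer;
   otherwise a stage-specific exponential time from diagnosis to breast
   cancer death competes with her other-cause death age.

The dwell distribution is piecewise-exponential per stage. This is the
simplest auditable choice; it is isolated behind the `dwell_rates`
parameter so heavier-tailed choices can be substituted without touching
the simulator.

## Screening overlay and common random numbers

A strategy is a biennial schedule `start-stop` (e.g. `"50-69"`). Each woman
receives a random 0/1-year phase offset with probability 1/2; this
*phase randomization* reproduces fractional expected round counts (strategy
45–69 has 13 rounds at phase 0 and 12 at phase 1, expected 12.5). At each
scheduled round a woman who is alive and not yet diagnosed attends with the
age-group coverage probability (1.0 in the base analyses). If a preclinical
tumour is present, it is detected with the *current stage's* sensitivity;
an attended screen without detection is a false-positive referral with the
age-band referral probability (`<50` vs `≥50`; a screen at exactly 50 uses
the older band). Misses are independent across rounds.

Every random draw a screening arm could need — attendance, detection and
referral uniforms per round, the survival quantile — is pre-sampled when
the histories are generated, from one seeded stream in a fixed, documented
order. Both arms therefore consume identical randomness (common random
numbers), which has two consequences:

* **exact null equivalence** — a test with zero sensitivity reproduces the
  no-screening outcome woman for woman, so incremental estimates are
  exactly zero, not zero in expectation;
* **sharply reduced Monte Carlo variance** of the incremental estimates,
  which are means of per-woman paired differences (their standard errors
  are reported alongside every estimate).

### Survival coupling

On screen detection, survival is re-resolved using the *same* per-woman
survival quantile with the cure probability of the earlier, detected stage
multiplied by `screen_benefit` (clamped at 1, and floored at the
clinical-diagnosis cure). The published evidence base for prognosis
improvement does not specify a mechanism, so the package makes the
conventional microsimulation choice: a breast cancer death occurs in the
screening arm only if it also occurred in the baseline arm *and* the shared
quantile exceeds the boosted cure; when it occurs, it occurs at the
baseline death age, i.e. lead time never moves the date of death. Screening
can consequently avert deaths but never cause them, per-woman dominance
holds (`death age (screening) ≥ death age (baseline)`), and life-years
gained are non-negative woman by woman. Screen-detected cases that would
never have surfaced clinically (the overdiagnosed) never die of breast
cancer.

## Parameters that matter

| parameter | units | default (fixtures) | role |
|---|---|---|---|
| `lambda_onset(age)` | /woman-year | logistic, plateau 0.0026–0.0048, midpoint 52, slope 0.15 | level of disease risk; drives benefit ordering across fixtures |
| `dwell_rates` | /year | DCIS 0.5, T1a 1.0, T1b 0.8, T1c 0.6 | mean preclinical sojourn per stage (2, 1, 1.25, 1.7 years) |
| `clinical_hazards` | /year | 0.03, 0.10, 0.25, 0.55, 1.20 | symptomatic surfacing; rises steeply with stage |
| `p_nonprogressive_dcis` | probability | 0.03 | fraction of DCIS that never progresses nor surfaces |
| `cure(stage, age)` | probability | 0.97 (DCIS) … 0.32 (T2+, 70+) | stage shift is the mechanism of benefit |
| `screen_benefit` | multiplier | 1.2 | extra cure on screen detection, same at all ages |
| `sensitivity(stage)` | probability | published programme values | detection given preclinical presence |
| `referral(<50, ≥50)` | probability | published programme values | false-positive rate per non-detected screen |
| `coverage(age group)` | probability | 1.0 (base); observed values for the variant | attendance per round, independent across rounds |

## The synthetic fixtures

The four shipped country bundles (`country_fixture()`,
`inst/extdata/*.yaml`) combine two very different kinds of numbers:

* **published policy parameters** — stage-specific sensitivities, referral
  rates by age band and observed examination coverage of the four
  exemplary national programmes — carried verbatim; and
* **synthetic natural-history, survival and demography parameters**. The
  calibrated national natural-history values are not public; the synthetic
  stand-ins were chosen *once* so that outcomes have the right order of
  magnitude under 50–69 biennial screening (single-digit overdiagnoses and
  deaths averted, hundreds of false positives and LYG per 1000 women,
  roughly 9000 screens per 1000) and preserve the published ordering of
  benefit across countries (Netherlands highest, Slovenia lowest). They
  are labelled SYNTHETIC in the fixture files and are not estimates of any
  country's epidemiology.

What the generator deliberately does **not** emulate: calendar-period and
birth-cohort effects (one 1975 cohort, no trends), breast-density
submodels, correlated misses across rounds for the same woman, persistent
never-attenders (attendance is redrawn each round), DCIS regression to
healthy, assessment cascades beyond the referral probability, and the
appendix-calibrated national parameter values themselves. Passing tests
therefore demonstrate the *mechanics* of the simulator and the *relative*
behaviour of strategies, not absolute agreement with any national
programme's published per-1000 levels; the published-table checks in the
test suite validate the outcome *arithmetic* (cumulative values, ratios,
rounding) on the published numbers directly.

## Calibration

`calibrate_sensitivities()` fits stage-specific sensitivities to
detection-rate targets (screen detections per 1000 screens by stage, plus
overall first-round and subsequent-round rates — the round split separates
sensitivity from the prevalent pool carried between rounds). The objective
is a weighted sum of squared relative deviations. Life histories are
generated once per calibration and reused for every evaluation, so the
objective is an exactly deterministic function of the parameters — without
common random numbers a simplex search would stall in simulation noise.

The optimizer is derivative-free: restarted Nelder–Mead with iterates
reflected ("folded") into [0, 1], alternated with cyclic one-dimensional
golden-section sweeps per sensitivity. The alternation matters because a
counting objective is piecewise constant at fine scales: a single simplex
run can collapse on a micro-plateau, and coordinate sweeps alone cannot
cross diagonal valleys. The loop stops when the budget of objective
evaluations is spent, the objective reaches zero, or a full cycle brings
no improvement. Setups with fewer targets than free parameters are
rejected as unidentifiable.

## Numerical choices and degenerate inputs

* One seeded stream with a fixed draw layout per cohort: identical
  `(params, n, seed)` reproduce a cohort bit-for-bit, and the paired arms
  are deterministic given the master seed.
* Table presentation rounds **half away from zero** (base R rounds half to
  even, which does not reproduce published cells): one decimal for counts
  and most ratios, three decimals for overdiagnoses per LYG.
* Zero denominators (no deaths averted or no LYG) raise a classed
  undefined-ratio condition rather than returning `Inf`/`NaN`.
* A strategy whose stop age does not exceed its start age, malformed life
  tables (`q` outside [0, 1], gaps in ages, terminal `q != 1`), unknown
  fixture names and unknown variants are rejected before any simulation.
* Zero dwell rates mean infinite dwell (no progression out of the stage);
  zero clinical hazards mean the stage never surfaces. T2+ never
  progresses regardless.
* The competing clocks use inverse-transform exponentials from reserved
  uniforms, so a second run with the same seed consumes the same draws
  even along different code paths.

## Problem sizes

The test suite runs cohorts of 10^4–10^5 women for distributional checks
(three Monte Carlo standard errors around exact or enumerated values) and
2 × 10^5 paired women for the directional strategy comparisons; the
acceptance script uses 10^5 for the null-identity and calibration-recovery
checks and 2 × 10^5 for the strategy runs. At these sizes the paired
incremental estimates are stable to roughly two significant figures, which
is what the qualitative (sign and ordering) assertions need.

## Worked sketch

```{r example}
library(screensim)

fi <- country_fixture("finland")
comp <- analyze_strategies(fi, c("50-69", "45-69", "50-74"),
                           n_women = 2e5, seed = 1)
build_outcome_table(comp)   # published-style table: reference + increments
percent_change_table(comp)  # ratio changes vs the 50-69 reference
autoplot(comp)              # bar chart of the percent changes

# Replay the outcome arithmetic on published per-1000 columns:
pub <- published_screening_outcomes()
build_outcome_table(pub[pub$country == "finland",
                        c("country", "strategy", "reference", "screens",
                          "overdiagnosed", "false_positives",
                          "deaths_averted", "lyg")])
```

## Known limitations

* Absolute per-1000 levels depend on the synthetic natural history and are
  not comparable to published national estimates; only the arithmetic and
  the qualitative structure are asserted.
* The attendance model has no persistent never-attender fraction, which
  understates between-woman variance in screens under partial coverage.
* The improvement of prognosis on screen detection is modelled as a cure
  multiplier with stage shift; hazard-reduction or stage-shift-only
  mechanisms would distribute the same average benefit differently over
  time.
* Only biennial presets are exercised against published round counts;
  other intervals are configurable but untested against external numbers.
* No costs or quality-of-life weights.
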