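# screensim

Individual-level microsimulation of the harms and benefits of mammography
screening, for epidemiologists and health-policy modellers comparing
screening age ranges.

A cohort of women is followed from age 45 to death twice, with and without
a screening programme, on *identical* simulated lives (common random
numbers). Each woman's life history consists of an other-cause death age
drawn from a life table; possibly an age at onset of a preclinical ductal
carcinoma in situ (DCIS) from an age-specific hazard λ(a); semi-Markov
progression DCIS → T1a → T1b → T1c → T2+, where in each stage an
exponential dwell clock (rate ρ_s) races an exponential clinical-surfacing
clock (rate η_s); a non-progressive DCIS fraction π that never progresses
nor surfaces; and a cure-model survival after diagnosis, cure(s, age), with
a stage-specific exponential time to breast cancer death otherwise.
Screening overlays a biennial schedule: attendance per round, detection
with stage-specific sensitivity Se_s, false-positive referral with an
age-band rate r, and on screen detection a cure probability
min(1, β · cure(s′, a′)) at the earlier detected stage s′ — screening can
avert a breast cancer death but never causes one, and never moves a death
earlier.

Per 1000 women, the package reports the published outcome set

* overdiagnoses `OD` — excess total diagnoses under lifelong follow-up,
* false positives `FP`,
* breast cancer deaths averted `DA`,
* life-years gained `LYG`,

and the four harm-to-benefit ratios `OD/DA`, `FP/DA`, `OD/LYG`, `FP/LYG`,
for the four biennial strategies 50–69 (reference), 45–69, 45–74 and
50–74. Stage-specific sensitivities can be calibrated to detection-rate
targets by a derivative-free search over the common-random-numbers
simulator.

## Worked example

```r
library(screensim)

fi <- country_fixture("finland")   # published policy parameters +
                                   # synthetic natural history
comp <- analyze_strategies(fi, c("50-69", "45-69", "50-74"),
                           n_women = 1e5, seed = 2026)
build_outcome_table(comp)
#> # A tibble: 3 × 11
#>   strategy reference screens overdiagnosed false_positives deaths_averted   lyg od_per_da fp_per_da od_per_lyg fp_per_lyg
#> 1 50-69    TRUE        9320.        2.32             258.           9.8   169.        0.2      26.4      0.014        1.5
#> 2 45-69    FALSE      11807.       -0.0200            74.8          0.880  24.3       0.2      31.2      0.012        1.7
#> 3 50-74    FALSE      11294.        0.98              55.5          2.69   25.2       0.3      25.1      0.017        1.6
```

The reference row is absolute versus no screening; the other rows are
increments over the reference (the published table layout). Read it as:
under 50–69 screening, 1000 women undergo ~9320 screens; 2.3 are
overdiagnosed and 258 have a false-positive referral, while 9.8 breast
cancer deaths are averted and 169 life-years gained. Starting at 45
(45–69) adds ~0.9 deaths averted and 24 life-years for ~75 extra false
positives and essentially no extra overdiagnosis; extending to 74 (50–74)
adds 2.7 deaths averted but ~1 extra overdiagnosed case. The ratio columns
are each strategy's cumulative harms over benefits.

```r
percent_change_table(comp)
#> # A tibble: 2 × 5
#>   strategy od_per_da fp_per_da od_per_lyg fp_per_lyg
#> 1 45-69        -9.03     18.3       -13.4      12.7
#> 2 50-74        11.6      -4.70       23.7       5.65
```

Starting earlier improves the overdiagnosis-related ratios (−9%, −13%) at
the cost of the false-positive-related ones; stopping later does the
opposite for overdiagnosis (+12%, +24%). `autoplot(comp)` draws these as a
bar chart.

The same table arithmetic replays published per-1000 columns directly:

```r
pub <- published_screening_outcomes()
build_outcome_table(pub[pub$country == "finland",
                        c("country", "strategy", "reference", "screens",
                          "overdiagnosed", "false_positives",
                          "deaths_averted", "lyg")])
#>   strategy  od_per_da fp_per_da od_per_lyg fp_per_lyg
#> 1 50-69           0.3      27.6      0.025        2
#> 2 45-74           0.4      31.9      0.028        2.4
#> 3 45-69           0.3      34        0.023        2.4
#> 4 50-74           0.4      25.9      0.032        2.1
```

Fixtures ship as editable YAML (`inst/extdata/*.yaml`,
`read_country_params()` / `write_country_params()`); their policy
parameters (sensitivities, referral rates, observed coverage) are
published programme values, while the natural-history, survival and
demography parameters are synthetic stand-ins — see the methods vignette
(`vignettes/screening-microsimulation.Rmd`) for the model, its
assumptions, and what the synthetic fixtures do and do not represent. A
thin command-line wrapper lives at `inst/cli/screensim.R`.

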