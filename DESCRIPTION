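Package: screensim
Title: Microsimulation of Harms and Benefits of Breast Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level microsimulation of breast cancer natural
    history (preclinical onset of ductal carcinoma in situ, semi-Markov
    stage progression, clinical surfacing, competing other-cause
    mortality) with mammography screening strategies overlaid on shared
    life histories via common random numbers. Computes, per 1000 women
    followed from age 45 to death, the incremental overdiagnoses,
    false-positive referrals, breast cancer deaths averted and life-years
    gained of biennial screening strategies with different age ranges,
    and the four harm-to-benefit ratios formed from them. Includes
    simulation-based calibration of stage-specific test sensitivities to
    detection-rate targets, synthetic country parameter fixtures, and
    table and figure style reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
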