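Package: psmce
Title: Partitioned-Survival Cost-Effectiveness Modelling from Published
    Kaplan-Meier Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rebuilds pseudo individual-patient data from digitized
    Kaplan-Meier coordinates and numbers at risk (the Guyot algorithm), fits
    and selects parametric survival families by AIC, applies network
    meta-analysis hazard ratios under proportional hazards, and runs a
    three-state (progression-free, progressed, dead) partitioned-survival
    cohort model to compare the cost-effectiveness of first-line systemic
    therapies for unresectable advanced hepatocellular carcinoma: discounted
    costs, life-years and QALYs, ICERs, dominance and the efficiency
    frontier, one-way (tornado) sensitivity analysis, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves. A
    synthetic-data layer simulates trial arms, digitization and model-input
    tables so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
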