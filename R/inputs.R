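# The shipped nine-strategy configuration. Dosing rules follow the published
# regimen table; per-mg prices, network-meta-analysis hazard ratios and
# adverse-event profiles are synthetic stand-ins (the originals live in
# supplementary tables that print no values) chosen once for a realistic
# cost/effect ordering. Every cost and probability parameter carries a
# +/-20% range for sensitivity analysis.

slug <- function(x) gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(x)))

shipped_strategies <- function(lenvatinib_rule = c("fixed_8mg",
                                                   "weight_threshold")) {
  lenvatinib_rule <- match.arg(lenvatinib_rule)
  lenva <- if (lenvatinib_rule == "fixed_8mg") {
    regimen_component("lenvatinib", "fixed", 8, "daily", price_per_mg = 12.6)
  } else {
    regimen_component("lenvatinib", "weight_threshold", 8, "daily",
                      price_per_mg = 12.6, dose_mg_high = 12,
                      threshold_kg = 60)
  }
  ae <- function(inc, cost, du) {
    tibble(event = "grade >=3 AE", incidence = inc, cost = cost,
           disutility = du)
  }
  list(
    strategy_spec(
      "Sorafenib",
      regimen_component("sorafenib", "fixed", 400, "daily",
                        price_per_mg = 0.032, admin_per_day = 2),
      hr_pfs = 1, hr_os = 1,
      ae_events = ae(0.45, 800, 0.06), testing_cost_per_cycle = 50
    ),
    strategy_spec(
      "Sunitinib",
      regimen_component("sunitinib", "fixed", 12.5, "daily",
                        price_per_mg = 0.95),
      hr_pfs = 0.62, hr_os = 0.60,
      ae_events = ae(0.50, 900, 0.07), testing_cost_per_cycle = 50
    ),
    strategy_spec(
      "Donafenib",
      regimen_component("donafenib", "fixed", 200, "daily",
                        price_per_mg = 0.34, admin_per_day = 2),
      hr_pfs = 0.80, hr_os = 0.76,
      ae_events = ae(0.38, 700, 0.05), testing_cost_per_cycle = 50
    ),
    strategy_spec(
      "Lenvatinib", lenva,
      hr_pfs = 0.61, hr_os = 0.55,
      ae_events = ae(0.57, 950, 0.07), testing_cost_per_cycle = 50
    ),
    strategy_spec(
      "Sorafenib plus Erlotinib",
      dplyr::bind_rows(
        regimen_component("sorafenib", "fixed", 400, "daily",
                          price_per_mg = 0.032, admin_per_day = 2),
        regimen_component("erlotinib", "fixed", 150, "daily",
                          price_per_mg = 0.85)
      ),
      hr_pfs = 0.63, hr_os = 0.57,
      ae_events = ae(0.55, 1000, 0.08), testing_cost_per_cycle = 50
    ),
    strategy_spec(
      "Linifanib",
      regimen_component("linifanib", "fixed", 17.5, "daily",
                        price_per_mg = 8.2),
      hr_pfs = 0.62, hr_os = 0.56,
      ae_events = ae(0.54, 1100, 0.07), testing_cost_per_cycle = 50
    ),
    strategy_spec(
      "Brivanib",
      regimen_component("brivanib", "fixed", 800, "daily",
                        price_per_mg = 0.19),
      hr_pfs = 0.64, hr_os = 0.56,
      ae_events = ae(0.52, 1000, 0.07), testing_cost_per_cycle = 50
    ),
    strategy_spec(
      "Sintilimab plus IBI305",
      dplyr::bind_rows(
        regimen_component("sintilimab", "fixed", 200, "every_k_weeks",
                          price_per_mg = 2.8, k_weeks = 3),
        regimen_component("IBI305", "per_kg", 15, "every_k_weeks",
                          price_per_mg = 0.60, k_weeks = 3)
      ),
      hr_pfs = 0.57, hr_os = 0.52,
      ae_events = ae(0.35, 1200, 0.05), testing_cost_per_cycle = 50
    ),
    strategy_spec(
      "Atezolizumab plus Bevacizumab",
      dplyr::bind_rows(
        regimen_component("atezolizumab", "fixed", 1200, "every_k_weeks",
                          price_per_mg = 4.5, k_weeks = 3),
        regimen_component("bevacizumab", "per_kg", 15, "every_k_weeks",
                          price_per_mg = 1.9, k_weeks = 3)
      ),
      hr_pfs = 0.58, hr_os = 0.53,
      ae_events = ae(0.36, 1300, 0.05), testing_cost_per_cycle = 50
    )
  )
}

#' Build the uncertain-parameter table of a configuration
#'
#' One row per model parameter: utilities (beta), per-cycle drug, testing,
#' second-line and adverse-event costs (gamma), AE disutilities (beta) and
#' hazard ratios (lognormal), each with a +/-20% range around its base
#' value. Parameter names are the ones the [build_ce_model()] closure
#' accepts as overrides.
#'
#' @param config A `ce_config` (see [make_model_inputs()]).
#' @return A tibble of [param_spec()] rows.
#' @export
build_param_specs <- function(config) {
  settings <- config$settings
  rows <- list(
    param_spec("u_pfs", config$utilities$u_pfs, psa_family = "beta",
               role = "utility"),
    param_spec("u_pd", config$utilities$u_pd, psa_family = "beta",
               role = "utility"),
    param_spec("c_second_line",
               cycle_drug_cost(config$second_line, settings),
               psa_family = "gamma", role = "cost"),
    param_spec("c_testing", config$strategies[[1]]$testing_cost_per_cycle,
               psa_family = "gamma", role = "cost")
  )
  for (s in config$strategies) {
    sl <- slug(s$name)
    ae <- ae_burden(s)
    rows <- c(rows, list(
      param_spec(paste0("c_drug_", sl), cycle_drug_cost(s, settings),
                 psa_family = "gamma", role = "cost"),
      param_spec(paste0("c_ae_", sl), ae$cost,
                 psa_family = "gamma", role = "cost"),
      param_spec(paste0("du_ae_", sl), ae$disutility,
                 psa_family = "beta", role = "probability")
    ))
    if (s$name != config$reference) {
      rows <- c(rows, list(
        param_spec(paste0("hr_pfs_", sl), s$hr_pfs,
                   psa_family = "lognormal", role = "hazard-ratio"),
        param_spec(paste0("hr_os_", sl), s$hr_os,
                   psa_family = "lognormal", role = "hazard-ratio")
      ))
    }
  }
  purrr::list_rbind(rows)
}

#' Shipped end-to-end model configuration
#'
#' Assembles the full analysis configuration: global settings, the nine
#' first-line strategies, the shared second-line regimen, utilities
#' 0.760/0.680, synthetic reference-arm curve sources (log-logistic PFS and
#' OS with medians 5.5 and 10.7 months, a shared shape of 1.5 so the PFS
#' curve never exceeds the OS curve, 450 patients, monthly digitization
#' with light jitter, risk table every 3 months), the +/-20% uncertain
#' parameter table, and PSA defaults (10,000 iterations).
#'
#' @param seed Root seed; all stage seeds derive from it.
#' @param n_psa PSA iteration count (default 10,000).
#' @param lenvatinib_rule `"fixed_8mg"` (default, following the published
#'   base case) or `"weight_threshold"` for the label dosing rule.
#' @return A `ce_config` list.
#' @export
make_model_inputs <- function(seed = 1, n_psa = 10000,
                              lenvatinib_rule = "fixed_8mg") {
  settings <- model_settings()
  strategies <- shipped_strategies(lenvatinib_rule)
  config <- structure(
    list(
      settings = settings,
      reference = "Sorafenib",
      strategies = strategies,
      second_line = second_line_spec(),
      utilities = utility_set(),
      curves = list(
        pfs = trial_arm_spec("Sorafenib PFS", "loglogistic",
                             c(scale = 5.5, shape = 1.5),
                             n_patients = 450, max_followup = 24,
                             seed = seed + 11),
        os = trial_arm_spec("Sorafenib OS", "loglogistic",
                            c(scale = 10.7, shape = 1.5),
                            n_patients = 450, max_followup = 36,
                            seed = seed + 12),
        grid_by = 1, jitter_sd = 0.005, risk_every = 3
      ),
      psa = list(n_iter = n_psa, seed = seed + 13),
      wtp_grid = seq(0, 100000, by = 5000),
      seed = seed
    ),
    class = "ce_config"
  )
  config$params <- build_param_specs(config)
  config
}

validate_config <- function(config) {
  if (!inherits(config, "ce_config")) abort("config must be a ce_config")
  names_ <- vapply(config$strategies, `[[`, character(1), "name")
  if (!config$reference %in% names_) {
    abort(paste0("reference strategy '", config$reference,
                 "' is not among the strategies"))
  }
  if (anyDuplicated(names_)) abort("duplicate strategy names in config")
  for (s in config$strategies) {
    if (is.null(s$hr_pfs) || is.null(s$hr_os)) {
      abort(paste0("strategy '", s$name,
                   "' needs both hr_pfs and hr_os (or its own curves)"))
    }
  }
  invisible(config)
}
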