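# Shared fixtures, computed once per run and cached.

fixture_env <- new.env(parent = emptyenv())

shipped_config <- function() {
  if (is.null(fixture_env$cfg)) {
    fixture_env$cfg <- make_model_inputs(seed = 42, n_psa = 500)
  }
  fixture_env$cfg
}

shipped_model <- function() {
  if (is.null(fixture_env$model)) {
    fixture_env$model <- suppressMessages(build_ce_model(shipped_config()))
  }
  fixture_env$model
}

# minimal two-strategy configuration with analytic exponential reference
# curves, bypassing the reconstruction stage; cheap enough for tight loops
toy_config <- function(hr_b = 0.7, price_b = 0.02) {
  ae <- tibble::tibble(event = "ae", incidence = 0.4, cost = 500,
                       disutility = 0.05)
  strategies <- list(
    strategy_spec("A",
                  regimen_component("a", "fixed", 100, "daily",
                                    price_per_mg = 0.01),
                  hr_pfs = 1, hr_os = 1, ae_events = ae,
                  testing_cost_per_cycle = 10),
    strategy_spec("B",
                  regimen_component("b", "fixed", 100, "daily",
                                    price_per_mg = price_b),
                  hr_pfs = hr_b, hr_os = hr_b, ae_events = ae,
                  testing_cost_per_cycle = 10)
  )
  cfg <- structure(
    list(
      settings = model_settings(),
      reference = "A",
      strategies = strategies,
      second_line = second_line_spec(),
      utilities = utility_set(),
      curves = NULL,
      psa = list(n_iter = 100, seed = 7),
      wtp_grid = seq(0, 80000, by = 10000),
      seed = 7
    ),
    class = "ce_config"
  )
  cfg$params <- build_param_specs(cfg)
  cfg
}

toy_reference_fits <- function() {
  list(
    pfs = list(selected = surv_dist("exponential", c(rate = 0.18))),
    os = list(selected = surv_dist("exponential", c(rate = 0.08)))
  )
}

toy_model <- function(cfg = toy_config()) {
  build_ce_model(cfg, reference_fits = toy_reference_fits())
}
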