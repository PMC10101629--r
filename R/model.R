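# Model closure: one end-to-end evaluation of the cohort model as a pure
# function of the uncertain parameters, for one-way and probabilistic
# sensitivity analysis. The baseline reference curves are reconstructed and
# fitted once; each evaluation then only re-powers the baseline survival by
# the drawn hazard ratios and re-accumulates, through the same kernel used
# by accumulate_ce().

#' Fit the reference survival curves of a configuration
#'
#' Runs the front half of the pipeline once: simulate (or load) the
#' reference arm for each endpoint, estimate its KM curve, digitize it,
#' reconstruct pseudo-IPD with the Guyot algorithm, fit all five parametric
#' families and select by AIC. The published analysis selected the
#' log-logistic family for the reference arm; a note is emitted when another
#' family wins on the data at hand.
#'
#' @param config A `ce_config` (see [make_model_inputs()]). `config$curves`
#'   holds either `trial_arm_spec`s (synthetic) or data frames of digitized
#'   coordinates plus risk tables.
#' @return A list with per-endpoint (`pfs`, `os`) selected fits, all fits,
#'   and reconstruction diagnostics.
#' @export
fit_reference_curves <- function(config) {
  cv <- config$curves
  fit_endpoint <- function(src, endpoint) {
    if (inherits(src, "trial_arm_spec")) {
      ipd <- simulate_arm(src)
      km <- km_curve(ipd)
      grid <- seq(0, floor(max(km$time)), by = cv$grid_by %||% 1)
      dig <- digitize_curve(km, grid, jitter_sd = cv$jitter_sd %||% 0,
                            seed = (src$seed %||% 0) + 1)
      risk <- risk_table(km, seq(0, max(grid) - 1e-9,
                                 by = cv$risk_every %||% 3))
      rec <- reconstruct_ipd(dig, risk)
    } else {
      rec <- reconstruct_ipd(src$curve, src$risk)
    }
    fits <- fit_all_families(rec)
    sel <- select_by_aic(fits)
    if (sel$family != "loglogistic") {
      inform(paste0(
        "AIC selected '", sel$family, "' for ", endpoint,
        " (the published reference analysis selected log-logistic)"
      ))
    }
    list(selected = sel, fits = fits, ipd = rec)
  }
  pfs <- fit_endpoint(cv$pfs, "PFS")
  os <- fit_endpoint(cv$os, "OS")
  list(pfs = pfs, os = os)
}

#' Build a fast model closure over the uncertain parameters
#'
#' Precomputes the baseline per-cycle survival of the reference arm and
#' returns a function `f(overrides)` that evaluates discounted cost, LYs and
#' QALYs for every strategy, with any subset of parameters (see
#' [build_param_specs()] for the names) overridden and the rest at base.
#' `f(NULL)` is the base case and agrees exactly with the
#' [build_trace()] + [accumulate_ce()] route.
#'
#' @param config A `ce_config`.
#' @param reference_fits Optional [fit_reference_curves()] result to reuse;
#'   computed on demand otherwise.
#' @return A function from a named numeric vector of overrides to a tibble
#'   with `strategy`, `cost`, `ly`, `qaly`. The fits used are attached as
#'   attribute `reference_fits`.
#' @export
build_ce_model <- function(config, reference_fits = NULL) {
  validate_config(config)
  settings <- config$settings
  if (is.null(reference_fits)) reference_fits <- fit_reference_curves(config)
  N <- n_cycles(settings)
  k <- 0:(N - 1)
  t_m <- k * cycle_months(settings)
  logS_pfs <- log(pmin(pmax(
    survival_at(reference_fits$pfs$selected, t_m), 1e-300), 1))
  logS_os <- log(pmin(pmax(
    survival_at(reference_fits$os$selected, t_m), 1e-300), 1))
  df <- discount_factor(k, settings)
  w <- cycle_weights(N, settings$half_cycle_correction)
  cycle_years <- settings$cycle_days / settings$days_per_year
  sl_active <- as.numeric(k < config$second_line$max_cycles)

  base_par <- setNames(config$params$base, config$params$name)
  strat <- purrr::map(config$strategies, function(s) {
    list(name = s$name, slug = slug(s$name),
         is_ref = s$name == config$reference)
  })

  n_s <- length(strat)
  strat_names <- vapply(strat, `[[`, character(1), "name")

  # hot path: plain numeric work only, one tibble built per call
  function(overrides = NULL) {
    par <- base_par
    if (!is.null(overrides)) {
      unknown <- setdiff(names(overrides), names(par))
      if (length(unknown) > 0) {
        abort(paste0("unknown parameter(s): ",
                     paste(unknown, collapse = ", ")))
      }
      par[names(overrides)] <- overrides
    }
    cost <- ly <- qaly <- numeric(n_s)
    for (j in seq_len(n_s)) {
      s <- strat[[j]]
      hr_p <- if (s$is_ref) 1 else par[[paste0("hr_pfs_", s$slug)]]
      hr_o <- if (s$is_ref) 1 else par[[paste0("hr_os_", s$slug)]]
      if (hr_p <= 0 || hr_o <= 0) abort("drawn hazard ratio <= 0")
      spfs <- exp(hr_p * logS_pfs)
      sos <- exp(hr_o * logS_os)
      totals <- ce_totals_kernel(
        pfs = pmin(spfs, sos), pd = pmax(sos - spfs, 0),
        df = df, cycle_years = cycle_years, w = w,
        c_first = par[[paste0("c_drug_", s$slug)]],
        c_second = par[["c_second_line"]],
        c_test = par[["c_testing"]], c_test_pd = par[["c_testing"]],
        u_pfs = par[["u_pfs"]], u_pd = par[["u_pd"]],
        ae_cost = par[[paste0("c_ae_", s$slug)]],
        ae_disutility = par[[paste0("du_ae_", s$slug)]],
        sl_active = sl_active
      )
      cost[j] <- totals[["cost"]]
      ly[j] <- totals[["ly"]]
      qaly[j] <- totals[["qaly"]]
    }
    out <- tibble(strategy = strat_names, cost = cost, ly = ly, qaly = qaly)
    attr(out, "reference_fits") <- reference_fits
    out
  }
}
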