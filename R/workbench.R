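# End-to-end drivers: base-case analysis (reconstruct -> fit -> adjust ->
# trace -> accumulate -> incremental + frontier) and the uncertainty
# analyses (tornado, PSA, CEAC), with optional CSV export and a run log.

#' Run the base-case cost-effectiveness analysis
#'
#' Executes the whole pipeline for every strategy in the configuration and
#' assembles the incremental table versus the reference and the efficiency
#' frontier. A run log records the selected survival families and AICs,
#' clamped progressed-state mass, seeds, and every default assumption
#' applied (cycle-timing convention, lenvatinib dosing, second-line cap).
#'
#' @param config A `ce_config`, e.g. [make_model_inputs()].
#' @param out_dir Optional directory; when given, writes
#'   `base_case.csv` (incremental table), `frontier.csv`, `fit_summary.csv`
#'   and `trace_<strategy>.csv` files plus `run_log.txt`.
#' @return A list of class `ce_analysis`: `results` (per-strategy cost / LY
#'   / QALY), `increments`, `frontier_table`, `reference_fits`, `traces`,
#'   `log`.
#' @export
run_base_case <- function(config, out_dir = NULL) {
  validate_config(config)
  settings <- config$settings
  reference_fits <- fit_reference_curves(config)
  log <- list(
    seed = config$seed,
    selected_family_pfs = reference_fits$pfs$selected$family,
    selected_family_os = reference_fits$os$selected$family,
    aic_pfs = reference_fits$pfs$selected$aic,
    aic_os = reference_fits$os$selected$aic,
    assumptions = c(
      paste0("cycle timing: state membership and discounting at cycle ",
             "starts; half-cycle correction ",
             if (settings$half_cycle_correction) "on" else "off"),
      "lenvatinib dosed per the shipped configuration (8 mg/day default)",
      paste0("second-line cost cap: ",
             if (is.finite(config$second_line$max_cycles))
               paste(config$second_line$max_cycles, "cycles")
             else "none"),
      "adverse-event costs and disutilities applied once at model entry"
    )
  )
  traces <- list()
  clamped <- numeric(0)
  rows <- purrr::map(config$strategies, function(s) {
    s_pfs <- apply_hr(reference_fits$pfs$selected, s$hr_pfs,
                      strategy = s$name, endpoint = "PFS")
    s_os <- apply_hr(reference_fits$os$selected, s$hr_os,
                     strategy = s$name, endpoint = "OS")
    tr <- suppressMessages(build_trace(s_pfs, s_os, settings,
                                       strategy = s$name))
    traces[[s$name]] <<- tr
    clamped[s$name] <<- attr(tr, "clamped_mass")
    accumulate_ce(tr, s, config$second_line, config$utilities, settings)
  })
  results <- purrr::list_rbind(rows)
  increments <- incremental_vs_reference(results, config$reference)
  frontier_table <- frontier(results)
  log$clamped_mass <- clamped
  out <- structure(
    list(
      results = results, increments = increments,
      frontier_table = frontier_table,
      reference_fits = reference_fits, traces = traces, log = log
    ),
    class = "ce_analysis"
  )
  if (!is.null(out_dir)) write_base_case(out, config, out_dir)
  out
}

write_base_case <- function(analysis, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format_ce_table(analysis$increments),
                   file.path(out_dir, "base_case.csv"), row.names = FALSE)
  utils::write.csv(analysis$frontier_table,
                   file.path(out_dir, "frontier.csv"), row.names = FALSE)
  fits <- c(analysis$reference_fits$pfs$fits, analysis$reference_fits$os$fits)
  utils::write.csv(
    dplyr::bind_rows(
      dplyr::mutate(fit_summary(analysis$reference_fits$pfs$fits),
                    endpoint = "PFS"),
      dplyr::mutate(fit_summary(analysis$reference_fits$os$fits),
                    endpoint = "OS")
    ),
    file.path(out_dir, "fit_summary.csv"), row.names = FALSE
  )
  for (nm in names(analysis$traces)) {
    tr <- analysis$traces[[nm]]
    tr$discount_factor <- discount_factor(tr$cycle, config$settings)
    utils::write.csv(tr, file.path(out_dir, paste0("trace_", slug(nm), ".csv")),
                     row.names = FALSE)
  }
  writeLines(
    c(
      paste0("seed: ", analysis$log$seed),
      paste0("selected family (PFS): ", analysis$log$selected_family_pfs,
             " AIC ", signif(analysis$log$aic_pfs, 8)),
      paste0("selected family (OS): ", analysis$log$selected_family_os,
             " AIC ", signif(analysis$log$aic_os, 8)),
      paste0("clamped PD mass by strategy: ",
             paste0(names(analysis$log$clamped_mass), "=",
                    signif(analysis$log$clamped_mass, 3), collapse = ", ")),
      "assumptions applied:",
      paste0("  - ", analysis$log$assumptions)
    ),
    file.path(out_dir, "run_log.txt")
  )
  invisible(analysis)
}

#' @export
print.ce_analysis <- function(x, ...) {
  cat("<ce_analysis> ", nrow(x$results), " strategies\n", sep = "")
  print(format_ce_table(x$increments))
  invisible(x)
}

#' Run the uncertainty analyses
#'
#' One-way (tornado) sensitivity for each non-reference strategy versus the
#' reference, a probabilistic sensitivity analysis of `config$psa$n_iter`
#' iterations, and cost-effectiveness acceptability curves over
#' `config$wtp_grid`.
#'
#' @param config A `ce_config`.
#' @param out_dir Optional directory for `tornado.csv`, `psa_scatter.csv`
#'   and `ceac.csv`.
#' @param tornado_pairs List of `c(strategy, comparator)` pairs for the
#'   tornado; defaults to every non-reference strategy versus the reference.
#' @param n_iter,seed Overrides for the PSA settings in the config.
#' @return A list of class `ce_uncertainty`: `tornado_tables` (named by
#'   `strategy vs comparator`), `psa` (a `psa_run`), `ceac_table`.
#' @export
run_uncertainty <- function(config, out_dir = NULL, tornado_pairs = NULL,
                            n_iter = NULL, seed = NULL) {
  validate_config(config)
  model <- build_ce_model(config)
  if (is.null(tornado_pairs)) {
    others <- setdiff(
      vapply(config$strategies, `[[`, character(1), "name"),
      config$reference
    )
    tornado_pairs <- lapply(others, function(s) c(s, config$reference))
  }
  tornado_tables <- lapply(tornado_pairs, function(p) {
    tornado(config$params, model, p)
  })
  names(tornado_tables) <- vapply(tornado_pairs,
                                  function(p) paste(p[1], "vs", p[2]),
                                  character(1))
  psa <- run_psa(model, config$params,
                 n_iter = n_iter %||% config$psa$n_iter,
                 seed = seed %||% config$psa$seed)
  ceac_table <- ceac(psa, config$wtp_grid)
  out <- structure(
    list(tornado_tables = tornado_tables, psa = psa,
         ceac_table = ceac_table),
    class = "ce_uncertainty"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    torn <- purrr::list_rbind(
      purrr::map2(tornado_tables, names(tornado_tables), function(tt, nm) {
        dplyr::mutate(as_tibble(tt), comparison = nm, .before = 1)
      })
    )
    utils::write.csv(torn, file.path(out_dir, "tornado.csv"),
                     row.names = FALSE)
    utils::write.csv(psa$results, file.path(out_dir, "psa_scatter.csv"),
                     row.names = FALSE)
    utils::write.csv(ceac_table, file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
  }
  out
}

#' Write / read an analysis configuration as JSON
#'
#' Round-trips the `ce_config` through JSON so configurations can be
#' version-controlled and shared. Function-free fields only; the curve
#' sources are stored as their specs.
#'
#' @param config A `ce_config`.
#' @param path File path.
#' @return `read_ce_config()` returns a `ce_config`; `write_ce_config()`
#'   returns the path invisibly.
#' @export
write_ce_config <- function(config, path) {
  validate_config(config)
  ser <- list(
    settings = unclass(config$settings),
    reference = config$reference,
    utilities = unclass(config$utilities),
    second_line = list(
      regimen = config$second_line$regimen,
      max_cycles = if (is.finite(config$second_line$max_cycles))
        config$second_line$max_cycles else "Inf"
    ),
    strategies = lapply(config$strategies, function(s) {
      list(name = s$name, regimen = s$regimen, hr_pfs = s$hr_pfs,
           hr_os = s$hr_os, ae_events = s$ae_events,
           testing_cost_per_cycle = s$testing_cost_per_cycle)
    }),
    curves = lapply(config$curves, function(cv) {
      if (inherits(cv, "trial_arm_spec")) {
        list(.type = "trial_arm_spec", name = cv$name,
             dist_family = cv$dist_family,
             dist_params = as.list(cv$dist_params),
             n_patients = cv$n_patients,
             max_followup = if (is.finite(cv$max_followup))
               cv$max_followup else "Inf",
             seed = cv$seed, dropout_rate = cv$dropout_rate)
      } else cv
    }),
    params = config$params,
    psa = config$psa,
    wtp_grid = config$wtp_grid,
    seed = config$seed
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ce_config
#' @export
read_ce_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  as_inf <- function(x) if (identical(x, "Inf")) Inf else x
  config <- structure(
    list(
      settings = do.call(model_settings, raw$settings),
      reference = raw$reference,
      utilities = do.call(utility_set, raw$utilities),
      second_line = second_line_spec(
        regimen = as_tibble(raw$second_line$regimen),
        max_cycles = as_inf(raw$second_line$max_cycles)
      ),
      strategies = lapply(raw$strategies, function(s) {
        strategy_spec(
          s$name, as_tibble(s$regimen), hr_pfs = s$hr_pfs, hr_os = s$hr_os,
          ae_events = as_tibble(s$ae_events),
          testing_cost_per_cycle = s$testing_cost_per_cycle
        )
      }),
      curves = lapply(raw$curves, function(cv) {
        if (is.list(cv) && identical(cv$.type, "trial_arm_spec")) {
          trial_arm_spec(cv$name, cv$dist_family, unlist(cv$dist_params),
                         n_patients = cv$n_patients,
                         max_followup = as_inf(cv$max_followup),
                         seed = cv$seed, dropout_rate = cv$dropout_rate)
        } else cv
      }),
      params = as_tibble(raw$params),
      psa = raw$psa,
      wtp_grid = raw$wtp_grid,
      seed = raw$seed
    ),
    class = "ce_config"
  )
  validate_config(config)
  config
}
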