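# Treatment-strategy descriptions: regimen components with dosing rules and
# unit prices, hazard ratios versus the reference arm, adverse-event
# profiles, and the shared second-line regimen applied during the
# progressed-disease state.

#' Describe one regimen component
#'
#' @param drug Drug name.
#' @param dose_type `"fixed"` (mg per administration), `"per_kg"` (mg/kg per
#'   administration) or `"weight_threshold"` (`dose_mg` below
#'   `threshold_kg`, `dose_mg_high` at or above it).
#' @param dose_mg Dose in mg (or mg/kg for `per_kg`); the low dose for
#'   `weight_threshold`.
#' @param schedule `"daily"` (with `admin_per_day` administrations a day) or
#'   `"every_k_weeks"` (one administration every `k_weeks` weeks).
#' @param price_per_mg Unit price, USD per mg.
#' @param admin_per_day Administrations per day for daily schedules.
#' @param k_weeks Weeks between administrations for `every_k_weeks`.
#' @param dose_mg_high,threshold_kg Weight-threshold rule parameters.
#' @return One-row tibble describing the component.
#' @export
regimen_component <- function(drug, dose_type, dose_mg, schedule,
                              price_per_mg, admin_per_day = 1, k_weeks = NA,
                              dose_mg_high = NA, threshold_kg = NA) {
  dose_type <- match.arg(dose_type, c("fixed", "per_kg", "weight_threshold"))
  schedule <- match.arg(schedule, c("daily", "every_k_weeks"))
  if (price_per_mg < 0) abort("price_per_mg must be >= 0")
  if (schedule == "every_k_weeks" && (is.na(k_weeks) || k_weeks <= 0)) {
    abort("every_k_weeks schedule needs k_weeks > 0")
  }
  tibble(
    drug = drug, dose_type = dose_type, dose_mg = dose_mg,
    dose_mg_high = dose_mg_high, threshold_kg = threshold_kg,
    schedule = schedule, admin_per_day = admin_per_day, k_weeks = k_weeks,
    price_per_mg = price_per_mg
  )
}

#' Define a first-line treatment strategy
#'
#' @param name Strategy label.
#' @param regimen Tibble of [regimen_component()] rows.
#' @param hr_pfs,hr_os Hazard ratios versus the reference strategy (> 0;
#'   1 for the reference itself).
#' @param ae_events Tibble with columns `event`, `incidence`, `cost`,
#'   `disutility`: grade >= 3 adverse events, their probability, one-off
#'   management cost (USD) and one-off QALY decrement.
#' @param testing_cost_per_cycle Routine testing/monitoring cost per cycle.
#' @return A `strategy_spec` list.
#' @export
strategy_spec <- function(name, regimen, hr_pfs = 1, hr_os = 1,
                          ae_events = NULL, testing_cost_per_cycle = 0) {
  if (hr_pfs <= 0 || hr_os <= 0) abort("hazard ratios must be > 0")
  if (is.null(ae_events)) {
    ae_events <- tibble(event = character(), incidence = numeric(),
                        cost = numeric(), disutility = numeric())
  }
  if (any(ae_events$incidence < 0 | ae_events$incidence > 1)) {
    abort("AE incidences must lie in [0, 1]")
  }
  if (any(ae_events$cost < 0)) abort("AE costs must be >= 0")
  structure(
    list(
      name = name, regimen = regimen, hr_pfs = hr_pfs, hr_os = hr_os,
      ae_events = ae_events, testing_cost_per_cycle = testing_cost_per_cycle
    ),
    class = "strategy_spec"
  )
}

#' Second-line regimen applied during progressed disease
#'
#' Default mirrors the guideline regimen used after progression:
#' camrelizumab 200 mg every 2 weeks plus apatinib 250 mg daily.
#'
#' @param regimen Tibble of [regimen_component()] rows.
#' @param max_cycles Optional cap on the number of cycles second-line cost
#'   accrues (default uncapped).
#' @return A `second_line_spec` list.
#' @export
second_line_spec <- function(regimen = NULL, max_cycles = Inf) {
  if (is.null(regimen)) {
    regimen <- dplyr::bind_rows(
      regimen_component("camrelizumab", "fixed", 200, "every_k_weeks",
                        price_per_mg = 2.35, k_weeks = 2),
      regimen_component("apatinib", "fixed", 250, "daily",
                        price_per_mg = 0.05)
    )
  }
  structure(list(regimen = regimen, max_cycles = max_cycles),
            class = "second_line_spec")
}

#' Health-state utilities
#'
#' @param u_pfs Utility of the progression-free state (default 0.760).
#' @param u_pd Utility of the progressed state (default 0.680).
#' @return A `utility_set` list. Warns if `u_pfs < u_pd`.
#' @export
utility_set <- function(u_pfs = 0.760, u_pd = 0.680) {
  if (u_pfs < 0 || u_pfs > 1 || u_pd < 0 || u_pd > 1) {
    abort("utilities must lie in [0, 1]")
  }
  if (u_pfs < u_pd) {
    warn("u_pfs < u_pd: progression-free utility is usually the larger")
  }
  structure(list(u_pfs = u_pfs, u_pd = u_pd), class = "utility_set")
}

regimen_cycle_cost <- function(regimen, settings,
                               body_weight_kg = settings$body_weight_kg) {
  if (nrow(regimen) == 0) return(0)
  mg <- numeric(nrow(regimen))
  for (i in seq_len(nrow(regimen))) {
    r <- regimen[i, ]
    per_admin <- switch(r$dose_type,
      fixed = r$dose_mg,
      per_kg = r$dose_mg * body_weight_kg,
      weight_threshold = if (body_weight_kg >= r$threshold_kg) r$dose_mg_high
                         else r$dose_mg,
      abort(paste0("unknown dose type '", r$dose_type, "'"))
    )
    admins <- switch(r$schedule,
      daily = r$admin_per_day * settings$cycle_days,
      every_k_weeks = settings$cycle_days / (7 * r$k_weeks),
      abort(paste0("unknown schedule '", r$schedule, "'"))
    )
    mg[i] <- per_admin * admins * r$price_per_mg
  }
  sum(mg)
}

#' Drug cost of one model cycle
#'
#' Sums component costs over a cycle: daily doses accrue
#' `admin_per_day x cycle_days` administrations; every-k-weeks dosing
#' accrues `cycle_days / (7k)` administrations per cycle (1 for q3w, 1.5
#' for q2w in a 21-day cycle). Per-kg doses use the baseline body weight
#' (60 kg by default).
#'
#' @param strategy A [strategy_spec()] or [second_line_spec()].
#' @param settings A [model_settings()].
#' @param body_weight_kg Body weight override (defaults to the settings
#'   value).
#' @return USD per cycle per person on treatment.
#' @examples
#' s <- strategy_spec("demo", regimen_component(
#'   "drug", "fixed", 100, "daily", price_per_mg = 1, admin_per_day = 2))
#' cycle_drug_cost(s, model_settings()) # 100 * 2 * 21 = 4200
#' @export
cycle_drug_cost <- function(strategy, settings,
                            body_weight_kg = settings$body_weight_kg) {
  if (!inherits(strategy, c("strategy_spec", "second_line_spec"))) {
    abort("strategy must be a strategy_spec or second_line_spec")
  }
  regimen_cycle_cost(strategy$regimen, settings, body_weight_kg)
}

#' Expected one-off adverse-event burden of a strategy
#'
#' @param strategy A [strategy_spec()].
#' @return A list with `cost` (expected USD) and `disutility` (expected QALY
#'   decrement), each the incidence-weighted sum over the AE profile.
#' @export
ae_burden <- function(strategy) {
  ae <- strategy$ae_events
  list(
    cost = sum(ae$incidence * ae$cost),
    disutility = sum(ae$incidence * ae$disutility)
  )
}
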