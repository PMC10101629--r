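# Discounted cost/LY/QALY accumulation over a cohort trace, incremental
# analysis versus the reference strategy, dominance and the efficiency
# frontier, and net monetary benefit.

# Shared accumulation kernel. Everything that turns state occupancies into
# totals goes through here, so the public accumulate_ce() route and the fast
# PSA closure cannot drift apart.
#   cost_k = pfs_k (c_first + c_test) + pd_k (c_second_k + c_test_pd)
#   qaly_k = (pfs_k u_pfs + pd_k u_pd) cycle_years
# both discounted at cycle starts; AE cost/disutility applied once at entry.
ce_totals_kernel <- function(pfs, pd, df, cycle_years, w,
                             c_first, c_second, c_test, c_test_pd,
                             u_pfs, u_pd, ae_cost, ae_disutility,
                             sl_active = NULL) {
  if (is.null(sl_active)) sl_active <- rep(1, length(pd))
  cost_cycle <- pfs * (c_first + c_test) +
    pd * (c_second * sl_active + c_test_pd)
  alive <- pfs + pd
  qaly_cycle <- (pfs * u_pfs + pd * u_pd) * cycle_years
  c(
    cost = sum(w * df * cost_cycle) + ae_cost,
    ly = sum(w * df * alive * cycle_years),
    qaly = sum(w * df * qaly_cycle) - ae_disutility
  )
}

cycle_weights <- function(n, half_cycle_correction) {
  w <- rep(1, n)
  if (half_cycle_correction && n >= 1) {
    w[1] <- 0.5
    w[n] <- 0.5
  }
  w
}

#' Accumulate discounted costs, life-years and QALYs over a trace
#'
#' Applies first-line drug plus testing cost to progression-free occupancy,
#' second-line drug plus testing cost to progressed occupancy, utilities
#' 0.760/0.680 by default via the supplied [utility_set()], and a one-off
#' expectation-weighted adverse-event cost and QALY decrement at model
#' entry. All streams are discounted at cycle starts.
#'
#' @param trace A [build_trace()] result for this strategy.
#' @param strategy The [strategy_spec()] that generated it.
#' @param second_line A [second_line_spec()].
#' @param utilities A [utility_set()].
#' @param settings The same [model_settings()] used for the trace.
#' @param testing_in_pd Apply the per-cycle testing cost during progressed
#'   disease as well (default `TRUE`).
#' @return A one-row tibble of class `ce_result`: `strategy`, `cost`, `ly`,
#'   `qaly`.
#' @export
accumulate_ce <- function(trace, strategy, second_line, utilities, settings,
                          testing_in_pd = TRUE) {
  tr_settings <- attr(trace, "settings")
  if (!is.null(tr_settings) && nrow(trace) != n_cycles(settings)) {
    abort("trace cycle count does not match the supplied settings")
  }
  ae <- ae_burden(strategy)
  df <- discount_factor(trace$cycle, settings)
  sl_active <- as.numeric(trace$cycle < second_line$max_cycles)
  totals <- ce_totals_kernel(
    pfs = trace$pfs, pd = trace$pd, df = df,
    cycle_years = settings$cycle_days / settings$days_per_year,
    w = cycle_weights(nrow(trace), settings$half_cycle_correction),
    c_first = cycle_drug_cost(strategy, settings),
    c_second = cycle_drug_cost(second_line, settings),
    c_test = strategy$testing_cost_per_cycle,
    c_test_pd = if (testing_in_pd) strategy$testing_cost_per_cycle else 0,
    u_pfs = utilities$u_pfs, u_pd = utilities$u_pd,
    ae_cost = ae$cost, ae_disutility = ae$disutility,
    sl_active = sl_active
  )
  out <- tibble(
    strategy = strategy$name,
    cost = totals[["cost"]], ly = totals[["ly"]], qaly = totals[["qaly"]]
  )
  structure(out, class = c("ce_result", class(out)))
}

#' Incremental analysis versus a reference strategy
#'
#' Computes incremental cost, incremental QALYs and the ICER of every
#' strategy against the named reference, preserving sign conventions: a
#' strategy that is cheaper and more effective than the reference is flagged
#' `"dominant"`, one that is costlier and less effective `"dominated"`, and
#' a zero QALY difference leaves the ICER undefined (`NA`).
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly` (one
#'   row per strategy; duplicate names are an error).
#' @param reference Label of the reference strategy.
#' @return A tibble with `strategy`, `cost`, `incr_cost`, `qaly`,
#'   `incr_qaly`, `comparator`, `icer`, `dominance`; the reference row has
#'   `NA` incrementals. `icer` is unrounded — use [format_ce_table()] for a
#'   publication-style table with whole-dollar ICERs.
#' @examples
#' res <- tibble::tibble(
#'   strategy = c("Sorafenib", "Sunitinib"),
#'   cost = c(9070, 9362), qaly = c(0.25, 0.78))
#' incremental_vs_reference(res, "Sorafenib")
#' @export
incremental_vs_reference <- function(results, reference) {
  if (anyDuplicated(results$strategy)) {
    abort("duplicate strategy names in results")
  }
  if (!reference %in% results$strategy) {
    abort(paste0("reference strategy '", reference, "' not found"))
  }
  ref <- results[results$strategy == reference, ]
  out <- as_tibble(results[, c("strategy", "cost", "qaly")])
  out$incr_cost <- out$cost - ref$cost
  out$incr_qaly <- out$qaly - ref$qaly
  out$comparator <- ifelse(out$strategy == reference, NA_character_, reference)
  out$icer <- ifelse(out$incr_qaly != 0, out$incr_cost / out$incr_qaly,
                     NA_real_)
  out$dominance <- dplyr::case_when(
    out$strategy == reference ~ "",
    out$incr_qaly > 0 & out$incr_cost <= 0 ~ "dominant",
    out$incr_qaly < 0 & out$incr_cost >= 0 ~ "dominated",
    out$incr_qaly == 0 ~ "icer undefined",
    .default = ""
  )
  out$icer[out$dominance %in% c("dominant", "dominated")] <- NA_real_
  out[, c("strategy", "cost", "incr_cost", "qaly", "incr_qaly",
          "comparator", "icer", "dominance")]
}

#' Efficiency frontier with dominance labels
#'
#' Sorts strategies by cost, removes strictly dominated ones (another
#' strategy costs no more and yields no fewer QALYs, at least one strictly),
#' then iteratively removes extendedly dominated ones (their sequential ICER
#' exceeds the next one along the frontier). Remaining frontier members
#' carry the ICER versus the next-cheaper frontier member.
#'
#' @param results Data frame with `strategy`, `cost`, `qaly` columns
#'   (>= 2 strategies).
#' @return A tibble sorted by cost with `dominance` in
#'   `{"", "dominated", "extended-dominated"}` and `icer` versus the
#'   previous frontier member (NA for the cheapest and for dominated rows).
#' @examples
#' icis <- tibble::tibble(
#'   strategy = c("Sintilimab plus IBI305", "Atezolizumab plus Bevacizumab"),
#'   cost = c(74083, 104188), qaly = c(0.85, 0.84))
#' frontier(icis)
#' @export
frontier <- function(results) {
  if (nrow(results) < 2) abort("frontier needs at least two strategies")
  if (anyDuplicated(results$strategy)) {
    abort("duplicate strategy names in results")
  }
  out <- as_tibble(results[, c("strategy", "cost", "qaly")])
  out <- dplyr::arrange(out, cost, dplyr::desc(qaly))
  n <- nrow(out)
  dominance <- rep("", n)
  for (i in seq_len(n)) {
    others <- out[-i, ]
    strict <- (others$cost <= out$cost[i] & others$qaly >= out$qaly[i]) &
      (others$cost < out$cost[i] | others$qaly > out$qaly[i])
    if (any(strict)) dominance[i] <- "dominated"
  }
  repeat {
    live <- which(dominance == "")
    if (length(live) < 3) break
    c_l <- out$cost[live]; q_l <- out$qaly[live]
    icers <- diff(c_l) / diff(q_l)
    drop <- which(icers[-length(icers)] > icers[-1])[1]
    if (is.na(drop)) break
    dominance[live[drop + 1]] <- "extended-dominated"
  }
  live <- which(dominance == "")
  icer <- rep(NA_real_, n)
  if (length(live) > 1) {
    icer[live[-1]] <- diff(out$cost[live]) / diff(out$qaly[live])
  }
  out$icer <- icer
  out$dominance <- dominance
  out
}

#' Net monetary benefit
#'
#' Adds `nmb = wtp x qaly - cost` to a results table. At the decision
#' threshold the highest-NMB strategy is the cost-effective choice; for a
#' pair with positive incremental QALYs the NMB ordering flips exactly at
#' `wtp` equal to their ICER.
#'
#' @param results Data frame with `cost` and `qaly` columns.
#' @param wtp Willingness-to-pay threshold, USD per QALY (>= 0).
#' @return The input tibble with an `nmb` column appended.
#' @export
net_monetary_benefit <- function(results, wtp) {
  if (wtp < 0) abort("wtp must be >= 0")
  dplyr::mutate(as_tibble(results), nmb = wtp * qaly - cost)
}

#' Publication-style incremental table
#'
#' Rounds costs and ICERs to whole dollars and QALYs to two decimals,
#' mirroring the layout of a base-case results table.
#'
#' @param increments An [incremental_vs_reference()] result.
#' @return A tibble with rounded display columns.
#' @export
format_ce_table <- function(increments) {
  dplyr::transmute(
    increments,
    strategy,
    cost = round(cost),
    incrC = round(incr_cost),
    QALY = round(qaly, 2),
    incrE = round(incr_qaly, 2),
    comparator = dplyr::coalesce(comparator, "/"),
    ICER = dplyr::if_else(dominance %in% c("dominant", "dominated"),
                          dominance, as.character(round(icer))),
    dominance
  )
}
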