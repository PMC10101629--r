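# Cycle costing, accumulation, incremental analysis, dominance and NMB.

test_that("cycle drug cost follows the dosing rules", {
  s <- model_settings()
  # fixed 100 mg twice daily at 1 USD/mg over 21 days
  bid <- strategy_spec("bid", regimen_component("d", "fixed", 100, "daily",
                                                price_per_mg = 1,
                                                admin_per_day = 2))
  expect_equal(cycle_drug_cost(bid, s), 4200)
  # 15 mg/kg q3w at 60 kg: one administration per cycle
  q3w <- strategy_spec("q3w", regimen_component("d", "per_kg", 15,
                                                "every_k_weeks",
                                                price_per_mg = 1,
                                                k_weeks = 3))
  expect_equal(cycle_drug_cost(q3w, s), 900)
  # q2w inside a 21-day cycle counts 1.5 administrations
  q2w <- strategy_spec("q2w", regimen_component("d", "fixed", 200,
                                                "every_k_weeks",
                                                price_per_mg = 1,
                                                k_weeks = 2))
  expect_equal(cycle_drug_cost(q2w, s), 300)
  free <- strategy_spec("free", regimen_component("d", "fixed", 100, "daily",
                                                  price_per_mg = 0))
  expect_equal(cycle_drug_cost(free, s), 0)
  broken <- bid
  broken$regimen$schedule <- "fortnightly"
  expect_error(cycle_drug_cost(broken, s), "unknown schedule")
  expect_error(regimen_component("d", "fixed", 1, "hourly", 1),
               "'arg' should be one of")
})

test_that("accumulation worked examples hold", {
  cfg <- toy_config()
  s <- cfg$settings
  # single-cycle horizon, everyone progression-free at utility 0.76
  s1 <- model_settings(horizon_years = 21 / 365.25)
  tr1 <- build_trace(function(t) ifelse(t == 0, 1, 1),
                     function(t) ifelse(t == 0, 1, 1), s1)
  noae <- strategy_spec("x", regimen_component("d", "fixed", 0, "daily",
                                               price_per_mg = 0))
  res1 <- accumulate_ce(tr1, noae, second_line_spec(), utility_set(), s1)
  expect_equal(res1$qaly, 0.76 * 21 / 365.25, tolerance = 1e-12)

  # cohort absorbed into death after cycle 0: only cycle-0 cost accrues
  dead_after_0 <- function(t) ifelse(t == 0, 1, 0)
  trd <- build_trace(dead_after_0, dead_after_0, s)
  one_cycle_drug <- strategy_spec(
    "y", regimen_component("d", "fixed", 10, "daily", price_per_mg = 1),
    testing_cost_per_cycle = 5)
  resd <- accumulate_ce(trd, one_cycle_drug, second_line_spec(),
                        utility_set(), s)
  expect_equal(resd$cost, 10 * 21 * 1 + 5)

  # utilities of 1 and no discounting make QALY = LY
  s0 <- model_settings(discount_rate_annual = 0)
  tr0 <- build_trace(surv_dist("exponential", c(rate = 0.18)),
                     surv_dist("exponential", c(rate = 0.08)), s0)
  res0 <- accumulate_ce(tr0, noae, second_line_spec(), utility_set(1, 1), s0)
  expect_equal(res0$qaly, res0$ly)
})

test_that("QALYs never exceed life-years and AE burden is one-off", {
  cfg <- toy_config()
  res <- toy_model(cfg)(NULL)
  expect_true(all(res$qaly <= res$ly))
  # removing the AE profile raises QALYs by exactly the expected decrement
  ae <- ae_burden(cfg$strategies[[1]])
  expect_equal(ae$cost, 0.4 * 500)
  expect_equal(ae$disutility, 0.4 * 0.05)
})

test_that("incremental analysis reproduces printed-table arithmetic", {
  res <- tibble::tibble(
    strategy = c("Sorafenib", "Sunitinib"),
    cost = c(9070, 9362), qaly = c(0.25, 0.78)
  )
  inc <- incremental_vs_reference(res, "Sorafenib")
  expect_equal(inc$incr_cost, c(0, 292))
  expect_equal(inc$incr_qaly, c(0, 0.53))
  expect_equal(round(inc$icer[2]), 551)
  tab <- format_ce_table(inc)
  expect_equal(tab$ICER[2], "551")
  expect_equal(tab$comparator, c("/", "Sorafenib"))

  # identical strategies: zero increments, undefined ICER
  same <- tibble::tibble(strategy = c("A", "B"), cost = c(10, 10),
                         qaly = c(1, 1))
  inc2 <- incremental_vs_reference(same, "A")
  expect_true(is.na(inc2$icer[2]))
  expect_equal(inc2$dominance[2], "icer undefined")

  # cheaper and more effective comparator is dominant
  dom <- tibble::tibble(strategy = c("A", "B"), cost = c(10, 5),
                        qaly = c(1, 2))
  expect_equal(incremental_vs_reference(dom, "A")$dominance[2], "dominant")
  expect_error(incremental_vs_reference(
    tibble::tibble(strategy = c("A", "A"), cost = 1:2, qaly = 1:2), "A"),
    "duplicate")
  expect_error(incremental_vs_reference(same, "Z"), "not found")
})

test_that("frontier removes strict and extended dominance correctly", {
  # printed-table worked examples
  icis <- tibble::tibble(
    strategy = c("Sintilimab plus IBI305", "Atezolizumab plus Bevacizumab"),
    cost = c(74083, 104188), qaly = c(0.85, 0.84))
  fr <- frontier(icis)
  expect_equal(fr$dominance[fr$strategy == "Atezolizumab plus Bevacizumab"],
               "dominated")
  tki <- tibble::tibble(
    strategy = c("Sunitinib", "Donafenib"),
    cost = c(9362, 33814), qaly = c(0.78, 0.45))
  expect_equal(frontier(tki)$dominance[2], "dominated")

  # three collinear strategies share sequential ICERs: middle retained
  col <- tibble::tibble(strategy = c("a", "b", "c"),
                        cost = c(0, 100, 200), qaly = c(0, 1, 2))
  expect_equal(frontier(col)$dominance, rep("", 3))
  expect_equal(frontier(col)$icer, c(NA, 100, 100))

  # extended dominance: b's sequential ICER exceeds c's
  ext <- tibble::tibble(strategy = c("a", "b", "c"),
                        cost = c(0, 150, 200), qaly = c(0, 0.5, 2))
  fre <- frontier(ext)
  expect_equal(fre$dominance[fre$strategy == "b"], "extended-dominated")
  # frontier ICERs strictly increase along strictly increasing cost/QALY
  live <- fre[fre$dominance == "", ]
  expect_true(all(diff(live$cost) > 0) && all(diff(live$qaly) > 0))

  # removing a dominated strategy leaves the frontier unchanged
  four <- tibble::tibble(strategy = c("a", "b", "c", "d"),
                         cost = c(0, 50, 150, 200),
                         qaly = c(0, 0.1, 1.5, 2))
  f1 <- frontier(four)
  drop <- f1$strategy[f1$dominance != ""][1]
  f2 <- frontier(four[four$strategy != drop, ])
  expect_equal(f2[f2$dominance == "", c("strategy", "cost", "qaly", "icer")],
               f1[f1$dominance == "", c("strategy", "cost", "qaly", "icer")])
})

test_that("net monetary benefit and ICER orderings are consistent", {
  res <- tibble::tibble(strategy = c("A", "B"), cost = c(1000, 3000),
                        qaly = c(0.5, 0.6))
  expect_equal(net_monetary_benefit(res, 0)$nmb, -res$cost)
  expect_equal(net_monetary_benefit(
    tibble::tibble(strategy = "x", cost = 0, qaly = 1), 37654.50)$nmb,
    37654.50)
  # NMB order flips exactly at the pairwise ICER (here 20000)
  icer <- (3000 - 1000) / (0.6 - 0.5)
  below <- net_monetary_benefit(res, icer - 1)
  above <- net_monetary_benefit(res, icer + 1)
  expect_gt(below$nmb[1], below$nmb[2])
  expect_lt(above$nmb[1], above$nmb[2])
  expect_error(net_monetary_benefit(res, -5), ">= 0")
})
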