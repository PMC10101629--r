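# One-way sensitivity, tornado ranking, PSA draws, and acceptability curves.

test_that("parameter draws match their specified moments", {
  specs <- dplyr::bind_rows(
    param_spec("fx", 5, psa_family = "fixed"),
    param_spec("cost", 100, psa_family = "gamma", role = "cost"),
    param_spec("util", 0.5, psa_family = "beta", role = "utility"),
    param_spec("hr", 0.7, psa_family = "lognormal", role = "hazard-ratio")
  )
  d <- draw_params(specs, n = 1e5, seed = 3)
  expect_equal(unique(d$fx), 5)
  # gamma: mean 100, sd (120-80)/3.92; 3 s.e. band
  sd_c <- (120 - 80) / (2 * qnorm(0.975))
  expect_lt(abs(mean(d$cost) - 100), 3 * sd_c / sqrt(1e5))
  expect_lt(abs(sd(d$cost) - sd_c), 0.05 * sd_c)
  expect_true(all(d$util > 0 & d$util < 1))
  expect_lt(abs(mean(d$util) - 0.5), 3 * sd(d$util) / sqrt(1e5))
  # lognormal HR: median at base
  expect_lt(abs(median(d$hr) - 0.7), 0.01)
  expect_true(all(d$hr > 0))
  # deterministic per seed
  expect_identical(draw_params(specs, n = 10, seed = 9),
                   draw_params(specs, n = 10, seed = 9))
  # degenerate range collapses to the base value
  dg <- draw_params(param_spec("u", 0.5, 0.5, 0.5, psa_family = "beta"),
                    n = 5, seed = 1)
  expect_equal(dg$u, rep(0.5, 5))
})

test_that("infeasible beta moment matching names the parameter", {
  bad <- param_spec("p_wild", 0.05, 0, 0.9, psa_family = "beta")
  expect_error(draw_params(bad, n = 2, seed = 1), "p_wild")
})

test_that("one-way analysis responds with the expected signs", {
  cfg <- toy_config()
  model <- toy_model(cfg)
  pair <- c("B", "A")

  # raising the reference drug price lowers the incremental cost of B vs A
  base_a <- cfg$params$base[cfg$params$name == "c_drug_a"]
  lo <- model(c(c_drug_a = 0.8 * base_a))
  hi <- model(c(c_drug_a = 1.2 * base_a))
  expect_gt(lo$cost[2] - lo$cost[1], hi$cost[2] - hi$cost[1])

  # raising u_pd raises incremental QALYs for the arm with more
  # progressed-state time (B has the lower hazard ratios)
  dq <- function(m) m$qaly[2] - m$qaly[1]
  expect_gte(dq(model(c(u_pd = 0.75))), dq(model(c(u_pd = 0.6))))
  expect_error(one_way(cfg$params, "nonexistent", model, pair),
               "unknown parameter")
})

test_that("tornado ranks parameters by ICER excursion width", {
  cfg <- toy_config()
  model <- toy_model(cfg)
  pair <- c("B", "A")
  tor <- tornado(cfg$params, model, pair)
  expect_equal(nrow(tor), nrow(cfg$params))
  expect_true(all(diff(tor$width) <= 0))
  expect_equal(tor$width, abs(tor$icer_high - tor$icer_low))
  # single parameter: a one-row table
  single <- tornado(cfg$params[cfg$params$name == "u_pd", ], model, pair)
  expect_equal(nrow(single), 1)
})

test_that("a parameter outside the comparator pair has zero tornado width", {
  model <- shipped_model()
  cfg <- shipped_config()
  keep <- cfg$params[cfg$params$name %in%
                       c("c_drug_sunitinib", "c_drug_donafenib"), ]
  tor <- tornado(keep, model, c("Sunitinib", "Sorafenib"))
  # donafenib's drug price cannot move a sunitinib-vs-sorafenib ICER
  expect_equal(tor$width[tor$parameter == "c_drug_donafenib"], 0)
  expect_gt(tor$width[tor$parameter == "c_drug_sunitinib"], 0)
  expect_equal(tor$parameter[1], "c_drug_sunitinib")
})

test_that("second-line price dominates an engineered tornado", {
  # strategy B progresses much earlier than it dies, so progressed-state
  # drug cost towers over everything else in the B-vs-A comparison
  cfg <- toy_config(hr_b = 0.4)
  model <- toy_model(cfg)
  keep <- cfg$params[cfg$params$name %in%
                       c("c_second_line", "c_testing", "u_pfs",
                         "c_ae_b", "du_ae_b"), ]
  tor <- tornado(keep, model, c("B", "A"))
  expect_equal(tor$parameter[1], "c_second_line")
})

test_that("PSA with degenerate distributions equals the base case", {
  cfg <- toy_config()
  model <- toy_model(cfg)
  fixed <- dplyr::mutate(cfg$params, psa_family = "fixed")
  run <- run_psa(model, fixed, n_iter = 5, seed = 2)
  base <- model(NULL)
  for (i in 1:5) {
    it <- run$results[run$results$iteration == i, ]
    expect_equal(it$cost, base$cost)
    expect_equal(it$qaly, base$qaly)
  }
  # n_iter = 1 runs a single evaluation
  expect_equal(nrow(run_psa(model, fixed, n_iter = 1, seed = 1)$results),
               nrow(base))
  # seed determinism of the full run
  r1 <- run_psa(model, cfg$params, n_iter = 20, seed = 5)
  r2 <- run_psa(model, cfg$params, n_iter = 20, seed = 5)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$samples, r2$samples)
})

test_that("PSA aborts when too many iterations fail", {
  specs <- param_spec("x", 1, 0.5, 2, psa_family = "lognormal")
  bad_model <- function(overrides = NULL) {
    if (!is.null(overrides) && overrides[["x"]] > 1) stop("precondition")
    tibble::tibble(strategy = "A", cost = 1, qaly = 1)
  }
  expect_error(run_psa(bad_model, specs, n_iter = 100, seed = 1), "failed")
})

test_that("CEAC probabilities are frequencies of highest NMB", {
  cfg <- toy_config()
  model <- toy_model(cfg)
  run <- run_psa(model, cfg$params, n_iter = 200, seed = 8)
  cc <- ceac(run, seq(0, 80000, by = 20000))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # wtp = 0: probability of being cheapest
  wide <- tidyr::pivot_wider(run$results, id_cols = iteration,
                             names_from = strategy, values_from = cost)
  p_a_cheapest <- mean(wide$A < wide$B) + 0.5 * mean(wide$A == wide$B)
  expect_equal(cc$probability[cc$wtp == 0 & cc$strategy == "A"],
               p_a_cheapest)
  # a strategy dominant in every iteration has a flat curve at 1
  fixed <- dplyr::mutate(cfg$params, psa_family = "fixed")
  run_fx <- run_psa(model, fixed, n_iter = 3, seed = 1)
  base <- model(NULL)
  winner <- base$strategy[which.max(37654.5 * base$qaly - base$cost)]
  cc_fx <- ceac(run_fx, 37654.5)
  expect_equal(cc_fx$probability[cc_fx$strategy == winner], 1)
  expect_error(ceac(run, numeric(0)), "empty")
})

test_that("CEAC matches a brute-force discrete-distribution oracle", {
  # two strategies; strategy A's cost takes four equally likely values.
  # Oracle: enumerate the four states and count where A is cost-saving.
  cost_a <- c(900, 1100, 1300, 1500)
  cost_b <- 1200
  qaly_a <- 0.5
  qaly_b <- 0.6
  oracle_p_a_saving <- mean(cost_a < cost_b) # 0.5
  run <- structure(
    list(
      results = tibble::tibble(
        iteration = rep(1:4, each = 2),
        strategy = rep(c("A", "B"), 4),
        cost = as.vector(rbind(cost_a, cost_b)),
        qaly = rep(c(qaly_a, qaly_b), 4)
      ),
      samples = NULL, n_iter = 4, seed = NULL, n_failed = 0
    ),
    class = "psa_run"
  )
  cc0 <- ceac(run, 0)
  expect_equal(cc0$probability[cc0$strategy == "A"], oracle_p_a_saving)
  # at wtp where NMB ties in every state are impossible, probabilities are
  # the enumerated NMB-win frequencies
  w <- 5000
  oracle_w <- mean(w * qaly_a - cost_a > w * qaly_b - cost_b)
  ccw <- ceac(run, w)
  expect_equal(ccw$probability[ccw$strategy == "A"], oracle_w)

  # symmetric cost difference centred at zero: 50/50 at the balancing wtp
  sym <- structure(
    list(results = tibble::tibble(
      iteration = rep(1:2, each = 2),
      strategy = rep(c("A", "B"), 2),
      cost = c(100, 200, 300, 200),
      qaly = rep(1, 4)
    ), samples = NULL, n_iter = 2, seed = NULL, n_failed = 0),
    class = "psa_run"
  )
  cs <- ceac(sym, 1000)
  expect_equal(cs$probability, c(0.5, 0.5), ignore_attr = TRUE)
})
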