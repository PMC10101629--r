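# Parametric likelihoods, MLE fitting, AIC selection and proportional-
# hazards adjustment.

test_that("log-likelihood matches closed forms", {
  ev <- tibble::tibble(time = c(1, 2, 3), event = 1)
  lam <- 0.37
  expect_equal(surv_loglik(ev, "exponential", c(rate = lam)),
               3 * log(lam) - 6 * lam)
  # all censored at T: n * log S(T)
  cen <- tibble::tibble(time = rep(7, 5), event = 0)
  expect_equal(surv_loglik(cen, "weibull", c(scale = 10, shape = 1.4)),
               5 * (-(7 / 10)^1.4))
  # weibull with shape 1 nests the exponential at rate = 1/scale
  mix <- tibble::tibble(time = c(0.5, 2, 3, 8), event = c(1, 1, 0, 1))
  expect_equal(surv_loglik(mix, "weibull", c(scale = 4, shape = 1)),
               surv_loglik(mix, "exponential", c(rate = 1 / 4)))
  expect_error(surv_loglik(tibble::tibble(time = c(-1, 2), event = 1),
                           "exponential", c(rate = 1)), "> 0")
})

test_that("exponential MLE equals the closed form d / sum(t)", {
  ev <- tibble::tibble(time = c(1, 2, 3), event = 1)
  fit <- fit_parametric(ev, "exponential")
  expect_equal(unname(fit$params["rate"]), 0.5, tolerance = 1e-6)
  # with censoring
  arm <- trial_arm_spec("e", "exponential", c(rate = 0.2),
                        n_patients = 400, max_followup = 12, seed = 8)
  ipd <- simulate_arm(arm)
  fit2 <- fit_parametric(ipd, "exponential")
  expect_equal(unname(fit2$params["rate"]),
               sum(ipd$event) / sum(ipd$time), tolerance = 1e-6)
  # AIC identity 2k - 2 logLik
  expect_equal(fit2$aic, 2 * 1 - 2 * fit2$loglik)
})

test_that("MLEs agree with survreg for the AFT-representable families", {
  arm <- trial_arm_spec("s", "weibull", c(scale = 10, shape = 1.4),
                        n_patients = 800, max_followup = 30, seed = 15)
  ipd <- simulate_arm(arm)
  df <- as.data.frame(ipd)
  for (fam in c("weibull", "lognormal", "loglogistic")) {
    fit <- fit_parametric(ipd, fam)
    sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = df,
                            dist = fam)
    if (fam == "lognormal") {
      expect_equal(unname(fit$params["meanlog"]), unname(coef(sr)),
                   tolerance = 1e-3)
      expect_equal(unname(fit$params["sdlog"]), sr$scale, tolerance = 1e-3)
    } else {
      # AFT: scale = exp(intercept), shape = 1/survreg scale
      expect_equal(unname(fit$params["scale"]), exp(unname(coef(sr))),
                   tolerance = 1e-3)
      expect_equal(unname(fit$params["shape"]), 1 / sr$scale,
                   tolerance = 1e-3)
    }
    expect_equal(fit$loglik, sr$loglik[1], tolerance = 1e-6)
    expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  }
})

test_that("each family recovers its generating parameters at n = 5000", {
  truth <- list(
    exponential = c(rate = 0.1),
    weibull = c(scale = 10, shape = 1.4),
    loglogistic = c(scale = 10, shape = 2),
    lognormal = c(meanlog = 2.2, sdlog = 0.8),
    gompertz = c(rate = 0.04, shape = 0.08)
  )
  n_seeds <- 20
  for (fam in names(truth)) {
    est <- matrix(NA_real_, n_seeds, length(truth[[fam]]))
    for (i in seq_len(n_seeds)) {
      arm <- trial_arm_spec(fam, fam, truth[[fam]], n_patients = 5000,
                            max_followup = 60, seed = 1000 + i)
      est[i, ] <- fit_parametric(simulate_arm(arm), fam)$params
    }
    bias <- abs(colMeans(est) / truth[[fam]] - 1)
    expect_lt(max(bias), 0.05, label = paste0(fam, " relative bias"))
  }
})

test_that("gompertz beats exponential on gompertz data", {
  arm <- trial_arm_spec("g", "gompertz", c(rate = 0.03, shape = 0.15),
                        n_patients = 1000, max_followup = 40, seed = 77)
  ipd <- simulate_arm(arm)
  expect_gte(fit_parametric(ipd, "gompertz")$loglik,
             fit_parametric(ipd, "exponential")$loglik)
})

test_that("AIC selection takes the minimum with the stated tie rules", {
  f <- function(family, aic, k = 2) {
    x <- surv_dist(family, switch(family,
      exponential = c(rate = 1),
      gompertz = c(rate = 1, shape = 1),
      lognormal = c(meanlog = 0, sdlog = 1),
      c(scale = 1, shape = 1)))
    x$aic <- aic
    x$n_params <- k
    x
  }
  expect_equal(select_by_aic(list(f("weibull", 100), f("loglogistic", 98),
                                  f("gompertz", 103)))$family, "loglogistic")
  # tie on AIC: fewer parameters wins
  expect_equal(select_by_aic(list(f("weibull", 98), f("exponential", 98,
                                                      k = 1)))$family,
               "exponential")
  # residual tie: fixed family order
  expect_equal(select_by_aic(list(f("gompertz", 98), f("weibull", 98)))$family,
               "weibull")
  expect_error(select_by_aic(list()), "no fits")
})

test_that("AIC selects the generating family in most replicates", {
  n_rep <- 50
  hits <- 0
  for (i in seq_len(n_rep)) {
    arm <- trial_arm_spec("a", "loglogistic", c(scale = 10, shape = 2),
                          n_patients = 1000, max_followup = 60,
                          seed = 5000 + i)
    sel <- select_by_aic(fit_all_families(simulate_arm(arm)))
    hits <- hits + (sel$family == "loglogistic")
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("hazard-ratio adjustment is a power of the baseline survival", {
  base <- surv_dist("loglogistic", c(scale = 10, shape = 2))
  expect_equal(survival_at(apply_hr(base, 1), c(2, 10, 30)),
               survival_at(base, c(2, 10, 30)))
  # S = 0.5 at the scale; HR 2 squares it
  expect_equal(survival_at(apply_hr(base, 2), 10), 0.25)
  # exponential family is closed under proportional hazards
  e <- surv_dist("exponential", c(rate = 0.3))
  expect_equal(survival_at(apply_hr(e, 0.5), c(1, 5, 20)),
               survival_at(surv_dist("exponential", c(rate = 0.15)),
                           c(1, 5, 20)))
  expect_error(apply_hr(base, 0), "positive")
  expect_error(apply_hr(base, -2), "positive")

  # hazard of the adjusted curve is hr x baseline hazard (numerical)
  hr <- 0.6
  adj <- apply_hr(base, hr)
  t <- seq(2, 30, by = 2)
  eps <- 1e-5
  h <- function(obj, t) {
    (log(survival_at(obj, t)) - log(survival_at(obj, t + eps))) / eps
  }
  expect_equal(h(adj, t), hr * h(base, t), tolerance = 1e-4)
})

test_that("survival evaluation respects its domain and closed forms", {
  ll <- surv_dist("loglogistic", c(scale = 7, shape = 1.3))
  expect_equal(survival_at(ll, 7), 0.5)
  expect_equal(survival_at(ll, 0), 1)
  expect_equal(survival_at(surv_dist("exponential", c(rate = 0.1)), 10),
               exp(-1))
  expect_error(survival_at(ll, -1), "t >= 0")
  for (fam in surv_families()) {
    fit <- surv_dist(fam, switch(fam,
      exponential = c(rate = 0.2),
      lognormal = c(meanlog = 1.5, sdlog = 0.7),
      gompertz = c(rate = 0.05, shape = 0.1),
      c(scale = 8, shape = 1.5)))
    s <- survival_at(fit, seq(0, 50, by = 0.5))
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("fit summaries are tidy", {
  arm <- trial_arm_spec("t", "weibull", c(scale = 8, shape = 1.2),
                        n_patients = 120, max_followup = 25, seed = 4)
  fits <- fit_all_families(simulate_arm(arm))
  tab <- fit_summary(fits)
  expect_named(tab, c("family", "param", "estimate", "loglik", "aic",
                      "selected"))
  expect_equal(sum(tab$selected) ,
               sum(tab$family == select_by_aic(fits)$family))
  td <- tidy(fits$weibull)
  expect_equal(td$term, c("scale", "shape"))
  gl <- glance(fits$weibull)
  expect_equal(gl$nobs, 120)
  expect_equal(gl$AIC, fits$weibull$aic)
})
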