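# Five parametric survival families with one fixed parameterization each:
#   exponential  S(t) = exp(-rate * t)                        params: rate
#   weibull      S(t) = exp(-(t/scale)^shape)                 params: scale, shape
#   loglogistic  S(t) = 1 / (1 + (t/scale)^shape)             params: scale, shape
#   lognormal    S(t) = 1 - Phi((log t - meanlog)/sdlog)      params: meanlog, sdlog
#   gompertz     S(t) = exp(-(rate/shape) * (exp(shape*t)-1)) params: rate, shape
# All scale/shape/rate parameters are strictly positive; lognormal meanlog is
# unconstrained. These formulas are the single source of truth package-wide.

#' Supported parametric survival families
#'
#' @return Character vector of the five family names, in the fixed order used
#'   for AIC tie-breaking: exponential, weibull, loglogistic, lognormal,
#'   gompertz.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "loglogistic", "lognormal", "gompertz")
}

surv_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("scale", "shape"),
    loglogistic = c("scale", "shape"),
    lognormal   = c("meanlog", "sdlog"),
    gompertz    = c("rate", "shape"),
    abort(paste0("unknown survival family: '", family, "'"))
  )
}

check_surv_params <- function(family, params) {
  wanted <- surv_param_names(family)
  if (!all(wanted %in% names(params))) {
    abort(paste0(
      "family '", family, "' needs named parameters: ",
      paste(wanted, collapse = ", ")
    ))
  }
  params <- params[wanted]
  positive <- if (family == "lognormal") "sdlog" else wanted
  bad <- positive[!is.finite(params[positive]) | params[positive] <= 0]
  if (length(bad) > 0) {
    abort(paste0(
      "inadmissible parameter(s) for family '", family, "': ",
      paste0(bad, " = ", signif(params[bad], 4), collapse = ", "),
      " (must be > 0)"
    ))
  }
  if (!all(is.finite(params))) abort("non-finite parameter value")
  params
}

# log S(t); vectorized over t, t >= 0
surv_logS <- function(family, params, t) {
  p <- params
  switch(family,
    exponential = -p[["rate"]] * t,
    weibull     = -(t / p[["scale"]])^p[["shape"]],
    loglogistic = -log1p((t / p[["scale"]])^p[["shape"]]),
    lognormal   = plnorm(t, p[["meanlog"]], p[["sdlog"]],
                         lower.tail = FALSE, log.p = TRUE),
    gompertz    = -(p[["rate"]] / p[["shape"]]) * expm1(p[["shape"]] * t)
  )
}

# log h(t) = log f(t) - log S(t); vectorized, t > 0
surv_logh <- function(family, params, t) {
  p <- params
  switch(family,
    exponential = rep(log(p[["rate"]]), length(t)),
    weibull     = log(p[["shape"]]) - log(p[["scale"]]) +
      (p[["shape"]] - 1) * (log(t) - log(p[["scale"]])),
    loglogistic = log(p[["shape"]]) - log(p[["scale"]]) +
      (p[["shape"]] - 1) * (log(t) - log(p[["scale"]])) -
      log1p((t / p[["scale"]])^p[["shape"]]),
    lognormal   = dlnorm(t, p[["meanlog"]], p[["sdlog"]], log = TRUE) -
      plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE, log.p = TRUE),
    gompertz    = log(p[["rate"]]) + p[["shape"]] * t
  )
}

# survival quantile: time at which S(t) = s, used by the arm simulator
surv_qtime <- function(family, params, s) {
  p <- params
  switch(family,
    exponential = -log(s) / p[["rate"]],
    weibull     = p[["scale"]] * (-log(s))^(1 / p[["shape"]]),
    loglogistic = p[["scale"]] * ((1 - s) / s)^(1 / p[["shape"]]),
    lognormal   = qlnorm(s, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    gompertz    = log1p(-p[["shape"]] / p[["rate"]] * log(s)) / p[["shape"]]
  )
}

#' Parametric survival log-likelihood for right-censored data
#'
#' Computes the censored-data log-likelihood
#' \eqn{\sum_{events} \log h(t_i) + \sum_{all} \log S(t_i)} under one of the
#' five supported families.
#'
#' @param ipd A data frame with columns `time` (months, > 0) and `event`
#'   (1 = event, 0 = censored), e.g. a [reconstruct_ipd()] or
#'   [simulate_arm()] result.
#' @param family One of [surv_families()].
#' @param params Named numeric vector of family parameters (see
#'   [fit_parametric()] for the parameterizations).
#' @return The log-likelihood (a single number).
#' @examples
#' ipd <- tibble::tibble(time = c(1, 2, 3), event = 1)
#' surv_loglik(ipd, "exponential", c(rate = 0.5)) # 3*log(0.5) - 3
#' @export
surv_loglik <- function(ipd, family, params) {
  family <- match.arg(family, surv_families())
  params <- check_surv_params(family, params)
  ipd <- validate_ipd(ipd)
  t <- ipd$time
  d <- ipd$event
  sum(d * surv_logh(family, params, t)) + sum(surv_logS(family, params, t))
}

validate_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd))) {
    abort("ipd must be a data frame with columns `time` and `event`")
  }
  if (nrow(ipd) == 0) abort("ipd has no records")
  if (any(!is.finite(ipd$time)) || any(ipd$time <= 0)) {
    abort("ipd times must be finite and > 0")
  }
  if (!all(ipd$event %in% c(0, 1))) abort("ipd event flags must be 0 or 1")
  ipd
}
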