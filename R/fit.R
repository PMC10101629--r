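# Maximum-likelihood fitting of the five parametric families, AIC model
# selection, and proportional-hazards adjustment of a fitted baseline.

moment_starts <- function(family, ipd) {
  t <- ipd$time
  ev <- ipd$event == 1
  d <- sum(ev)
  lt <- log(t[ev])
  s_lt <- if (d > 1) sd(lt) else 1
  s_lt <- max(s_lt, 0.1)
  base <- switch(family,
    exponential = c(rate = d / sum(t)),
    # sd(log T) for Weibull is ~1.283/shape; geometric mean event time ~ scale
    weibull     = c(scale = exp(mean(lt)), shape = 1.283 / s_lt),
    # logistic log-time sd is pi/(sqrt(3) shape)
    loglogistic = c(scale = exp(median(lt)), shape = 1.814 / s_lt),
    lognormal   = c(meanlog = mean(lt), sdlog = s_lt),
    gompertz    = c(rate = d / sum(t), shape = 0.05)
  )
  list(base, base * c(0.5, 2)[seq_along(base) %% 2 + 1], base * 1.5)
}

# positivity via log transform; lognormal meanlog stays on the real line
to_working <- function(family, params) {
  if (family == "lognormal") c(params[["meanlog"]], log(params[["sdlog"]]))
  else log(params)
}

from_working <- function(family, theta) {
  nm <- surv_param_names(family)
  p <- if (family == "lognormal") c(theta[1], exp(theta[2])) else exp(theta)
  setNames(p, nm)
}

#' Fit one parametric survival family by maximum likelihood
#'
#' Maximizes the right-censored log-likelihood (see [surv_loglik()]) by
#' quasi-Newton search on log-transformed parameters, from three
#' moment-based starting points. Parameterizations:
#' \describe{
#'   \item{exponential}{\eqn{S(t) = e^{-\lambda t}}; parameter `rate`.}
#'   \item{weibull}{\eqn{S(t) = \exp(-(t/\alpha)^\beta)}; `scale`, `shape`.}
#'   \item{loglogistic}{\eqn{S(t) = 1/(1 + (t/\alpha)^\beta)}; `scale`,
#'     `shape`; the scale is the median survival time.}
#'   \item{lognormal}{\eqn{S(t) = 1 - \Phi((\log t - \mu)/\sigma)};
#'     `meanlog`, `sdlog`.}
#'   \item{gompertz}{\eqn{S(t) = \exp(-(\lambda/\gamma)(e^{\gamma t} - 1))};
#'     `rate`, `shape` (> 0).}
#' }
#'
#' @param ipd Data frame with `time`/`event` columns; at least one event is
#'   required for the two-parameter families.
#' @param family One of [surv_families()].
#' @return A `surv_fit` object: family, named `params`, `loglik`, `aic`
#'   (\eqn{2k - 2\log L}), `n_params`, `n`, `n_event`.
#' @examples
#' ipd <- tibble::tibble(time = c(1, 2, 3), event = 1)
#' fit_parametric(ipd, "exponential")$params # rate = 3/6
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, surv_families())
  ipd <- validate_ipd(ipd)
  n_event <- sum(ipd$event)
  k <- length(surv_param_names(family))
  if (n_event < 1 && k > 1) {
    abort(paste0("family '", family,
                 "' needs at least one event to identify its shape"))
  }
  if (n_event < 1) abort("cannot fit with zero events")
  nll <- function(theta) {
    p <- from_working(family, theta)
    ll <- suppressWarnings(try(
      surv_loglik(ipd, family, p), silent = TRUE
    ))
    if (inherits(ll, "try-error") || !is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  for (start in moment_starts(family, ipd)) {
    th0 <- to_working(family, check_surv_params(family, start))
    opt <- if (k == 1) {
      o <- optimise(nll, interval = th0 + c(-8, 8), tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0)
    } else {
      suppressWarnings(optim(th0, nll, method = "Nelder-Mead",
                             control = list(maxit = 2000, reltol = 1e-12)))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e10) {
    abort(paste0(
      "maximum-likelihood fit for family '", family, "' did not converge; ",
      "best objective ", signif(best$value %||% NA, 6)
    ))
  }
  # polish with a second Nelder-Mead pass from the best start
  if (k > 1) {
    opt2 <- suppressWarnings(optim(best$par, nll, method = "Nelder-Mead",
                                   control = list(maxit = 2000,
                                                  reltol = 1e-12)))
    if (opt2$value < best$value) best <- opt2
  }
  params <- from_working(family, best$par)
  loglik <- -best$value
  structure(
    list(
      family = family, params = params, loglik = loglik,
      n_params = k, aic = 2 * k - 2 * loglik,
      n = nrow(ipd), n_event = n_event,
      arm_label = attr(ipd, "arm_label")
    ),
    class = "surv_fit"
  )
}

#' Fit all five families to the same data
#'
#' @param ipd Data frame with `time`/`event` columns.
#' @param families Families to fit (default all five).
#' @return A named list of `surv_fit` objects.
#' @export
fit_all_families <- function(ipd, families = surv_families()) {
  fits <- lapply(families, function(f) fit_parametric(ipd, f))
  setNames(fits, families)
}

#' Select the best fit by Akaike information criterion
#'
#' Returns the minimum-AIC fit. Exact AIC ties go to the fit with fewer
#' parameters; any residual tie is broken by the fixed family order of
#' [surv_families()].
#'
#' @param fits A (list of) `surv_fit` objects, e.g. [fit_all_families()].
#' @return The selected `surv_fit`.
#' @export
select_by_aic <- function(fits) {
  if (inherits(fits, "surv_fit")) fits <- list(fits)
  if (length(fits) == 0) abort("no fits to select from")
  ord <- order(
    vapply(fits, `[[`, numeric(1), "aic"),
    vapply(fits, `[[`, numeric(1), "n_params"),
    match(vapply(fits, `[[`, character(1), "family"), surv_families())
  )
  fits[[ord[1]]]
}

#' Construct a parametric survival curve from known parameters
#'
#' Wraps known parameter values (e.g. estimates published elsewhere, or the
#' truth behind a synthetic arm) in the same object [fit_parametric()]
#' returns, so they can be evaluated with [survival_at()], HR-adjusted with
#' [apply_hr()] and fed to [build_trace()]. Likelihood fields are `NA`.
#'
#' @param family One of [surv_families()].
#' @param params Named numeric parameter vector for that family.
#' @return A `surv_fit` object without likelihood information.
#' @export
surv_dist <- function(family, params) {
  family <- match.arg(family, surv_families())
  params <- check_surv_params(family, params)
  structure(
    list(family = family, params = params, loglik = NA_real_,
         n_params = length(params), aic = NA_real_,
         n = NA_integer_, n_event = NA_integer_, arm_label = NULL),
    class = "surv_fit"
  )
}

#' Adjust a fitted survival curve by a hazard ratio
#'
#' Under proportional hazards, \eqn{S_{adj}(t) = S_{base}(t)^{HR}}: a hazard
#' ratio below 1 lifts the curve, above 1 lowers it. Used to derive
#' comparator-arm curves from the reference fit and network meta-analysis
#' hazard ratios.
#'
#' @param base A `surv_fit` (or another `surv_adjusted`).
#' @param hr Hazard ratio (> 0).
#' @param strategy,endpoint Optional labels carried into the result.
#' @return A `surv_adjusted` object.
#' @export
apply_hr <- function(base, hr, strategy = NULL, endpoint = NULL) {
  if (!is.numeric(hr) || length(hr) != 1 || !is.finite(hr) || hr <= 0) {
    abort("hazard ratio must be a single positive number")
  }
  if (inherits(base, "surv_adjusted")) {
    return(apply_hr(base$base, hr * base$hr, strategy %||% base$strategy,
                    endpoint %||% base$endpoint))
  }
  if (!inherits(base, "surv_fit")) abort("base must be a surv_fit")
  structure(
    list(base = base, hr = hr, strategy = strategy, endpoint = endpoint),
    class = "surv_adjusted"
  )
}

#' @export
survival_at.surv_fit <- function(object, t) {
  exp(surv_logS(object$family, object$params, t))
}

#' @export
survival_at.surv_adjusted <- function(object, t) {
  exp(object$hr * surv_logS(object$base$family, object$base$params, t))
}

#' @export
print.surv_fit <- function(x, ...) {
  cat("<surv_fit> ", x$family, "  (n = ", x$n, ", events = ", x$n_event,
      ")\n", sep = "")
  cat("  params:", paste0(names(x$params), " = ", signif(x$params, 5),
                          collapse = ", "), "\n")
  cat("  logLik:", signif(x$loglik, 6), "  AIC:", signif(x$aic, 6), "\n")
  invisible(x)
}

#' @export
print.surv_adjusted <- function(x, ...) {
  cat("<surv_adjusted> ", x$base$family, " baseline, HR = ", x$hr, "\n",
      sep = "")
  invisible(x)
}

#' Tidy a parametric survival fit
#'
#' @param x A `surv_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.surv_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a parametric survival fit
#'
#' @param x A `surv_fit`.
#' @param ... Unused.
#' @return A tibble with `family`, `logLik`, `AIC`, `nobs`, `n_event`.
#' @export
glance.surv_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$loglik, AIC = x$aic,
         nobs = x$n, n_event = x$n_event)
}

#' Fit summary table across families
#'
#' Long-format export matching the CSV schema
#' `family,param,estimate,loglik,aic,selected`.
#'
#' @param fits Named list from [fit_all_families()].
#' @return A tibble, one row per family x parameter.
#' @export
fit_summary <- function(fits) {
  sel <- select_by_aic(fits)$family
  purrr::map(fits, function(f) {
    tibble(
      family = f$family, param = names(f$params),
      estimate = unname(f$params), loglik = f$loglik, aic = f$aic,
      selected = f$family == sel
    )
  }) |> purrr::list_rbind()
}
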