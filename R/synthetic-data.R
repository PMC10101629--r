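# Synthetic trial layer: simulated arms with administrative censoring, the
# Kaplan-Meier step estimator, and grid digitization. These stand in for the
# published curves a real analysis would digitize from trial figures.

#' Specify a synthetic trial arm
#'
#' Describes one arm drawn from a known parametric survival distribution with
#' administrative censoring at `max_followup`, so downstream stages
#' (digitization, reconstruction, fitting) can be tested against known truth.
#'
#' @param name Arm label.
#' @param dist_family One of [surv_families()].
#' @param dist_params Named numeric vector of parameters for that family.
#' @param n_patients Number of subjects (>= 1).
#' @param max_followup Administrative censoring time in months (> 0; `Inf`
#'   for complete follow-up).
#' @param seed Optional integer seed making [simulate_arm()] deterministic.
#' @param dropout_rate Optional uniform-dropout hazard (per month); defaults
#'   to 0 (administrative censoring only).
#' @return A `trial_arm_spec` list.
#' @export
trial_arm_spec <- function(name, dist_family, dist_params, n_patients,
                           max_followup = Inf, seed = NULL,
                           dropout_rate = 0) {
  dist_family <- match.arg(dist_family, surv_families())
  dist_params <- check_surv_params(dist_family, dist_params)
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("n_patients must be >= 1")
  }
  if (!is.numeric(max_followup) || max_followup <= 0) {
    abort("max_followup must be > 0")
  }
  if (dropout_rate < 0) abort("dropout_rate must be >= 0")
  structure(
    list(
      name = name, dist_family = dist_family, dist_params = dist_params,
      n_patients = as.integer(n_patients), max_followup = max_followup,
      seed = seed, dropout_rate = dropout_rate
    ),
    class = "trial_arm_spec"
  )
}

#' Simulate pseudo individual-patient data for one arm
#'
#' Draws event times by inverse-transform sampling from the arm's survival
#' function; times beyond `max_followup` are administratively censored there.
#' With a `seed` in the spec the output is reproducible.
#'
#' @param spec A [trial_arm_spec()].
#' @return A tibble with columns `time` (months) and `event` (1 event,
#'   0 censored), of class `pseudo_ipd`; the arm label is kept in the
#'   `arm_label` attribute.
#' @examples
#' arm <- trial_arm_spec("ref", "exponential", c(rate = 0.1),
#'                       n_patients = 50, max_followup = 24, seed = 1)
#' simulate_arm(arm)
#' @export
simulate_arm <- function(spec) {
  if (!inherits(spec, "trial_arm_spec")) {
    abort("spec must be a trial_arm_spec")
  }
  draw <- function() {
    u <- runif(spec$n_patients)
    t <- surv_qtime(spec$dist_family, spec$dist_params, u)
    t <- pmax(t, .Machine$double.eps) # S ~ 1 draws can hit exactly 0
    event <- rep(1L, spec$n_patients)
    if (spec$dropout_rate > 0) {
      drop_t <- -log(runif(spec$n_patients)) / spec$dropout_rate
      event[drop_t < t] <- 0L
      t <- pmin(t, drop_t)
    }
    censored <- t > spec$max_followup
    t[censored] <- spec$max_followup
    event[censored] <- 0L
    tibble(time = t, event = event)
  }
  out <- if (is.null(spec$seed)) draw() else withr::with_seed(spec$seed, draw())
  new_pseudo_ipd(out, arm_label = spec$name)
}

new_pseudo_ipd <- function(df, arm_label = NULL, approximate = FALSE,
                           diagnostics = NULL) {
  out <- as_tibble(df)
  class(out) <- c("pseudo_ipd", class(out))
  attr(out, "arm_label") <- arm_label
  attr(out, "approximate") <- approximate
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Kaplan-Meier curve of pseudo individual-patient data
#'
#' Product-limit estimate via [survival::survfit()], returned as a tidy step
#' curve starting at (0, 1). Evaluate it with [survival_at()]; number-at-risk
#' tables come from [risk_table()].
#'
#' @param ipd Data frame with `time` and `event` columns (at least one row).
#' @return A tibble of class `km_curve` with columns `time`, `survival`,
#'   `n_risk`, `n_event`; the underlying records are kept as an attribute so
#'   risk tables can be computed at arbitrary times.
#' @export
km_curve <- function(ipd) {
  ipd <- validate_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ipd))
  steps <- tibble(
    time = c(0, fit$time),
    survival = c(1, fit$surv),
    n_risk = c(nrow(ipd), fit$n.risk),
    n_event = c(0, fit$n.event)
  )
  out <- structure(steps, class = c("km_curve", class(steps)))
  attr(out, "ipd") <- tibble(time = ipd$time, event = ipd$event)
  attr(out, "arm_label") <- attr(ipd, "arm_label")
  out
}

#' Numbers at risk at given times
#'
#' @param x A `km_curve` or a data frame of `time`/`event` records.
#' @param times Interval start times (months, nondecreasing).
#' @return A tibble with columns `interval_start` and `n_risk` (subjects with
#'   observation time >= the interval start).
#' @export
risk_table <- function(x, times) {
  rec <- if (inherits(x, "km_curve")) attr(x, "ipd") else validate_ipd(x)
  if (is.unsorted(times)) abort("risk-table times must be nondecreasing")
  tibble(
    interval_start = times,
    n_risk = vapply(times, function(s) sum(rec$time >= s), integer(1))
  )
}

km_stepfun <- function(curve) {
  stepfun(curve$time[-1], curve$survival, right = FALSE)
}

#' Evaluate a survival curve or fit
#'
#' @param object A `km_curve`, `surv_fit`, `surv_adjusted`, or a plain
#'   function of time.
#' @param t Times in months (>= 0).
#' @return Survival probabilities in \[0, 1\].
#' @export
survival_at <- function(object, t) {
  if (any(t < 0)) abort("survival is only defined for t >= 0")
  UseMethod("survival_at")
}

#' @export
survival_at.km_curve <- function(object, t) km_stepfun(object)(t)

#' @export
survival_at.digitized_curve <- function(object, t) {
  left <- if (object$time[1] > 0) 1 else object$survival[1]
  stepfun(object$time, c(left, object$survival), right = FALSE)(t)
}

#' @export
survival_at.function <- function(object, t) object(t)

#' Digitize a survival curve on a time grid
#'
#' Emulates manual extraction of coordinates from a published figure: the
#' curve is read at each grid time, optional probability-scale jitter is
#' added, and the result is clipped to \[0, 1\] and forced nonincreasing by
#' isotonic clipping (running minimum). With `jitter_sd = 0` the grid values
#' reproduce the curve exactly.
#'
#' @param curve A `km_curve` (or anything [survival_at()] accepts).
#' @param grid Strictly increasing times within the curve's support.
#' @param jitter_sd Standard deviation of Gaussian noise on the probability
#'   scale (default 0).
#' @param seed Optional seed for reproducible jitter.
#' @return A tibble of class `digitized_curve` with columns `time`,
#'   `survival`.
#' @export
digitize_curve <- function(curve, grid, jitter_sd = 0, seed = NULL) {
  if (length(grid) == 0) abort("empty digitization grid")
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("digitization grid must be strictly increasing")
  }
  if (inherits(curve, "km_curve") && max(grid) > max(curve$time)) {
    abort("digitization grid extends beyond the curve's support")
  }
  s <- survival_at(curve, grid)
  if (jitter_sd > 0) {
    noise <- function() stats::rnorm(length(grid), 0, jitter_sd)
    s <- s + if (is.null(seed)) noise() else withr::with_seed(seed, noise())
  }
  s <- pmin(pmax(s, 0), 1)
  s <- cummin(if (grid[1] > 0) s else c(1, s[-1])) # isotonic, anchored at 1
  out <- tibble(time = grid, survival = s)
  structure(out, class = c("digitized_curve", class(out)),
            arm_label = attr(curve, "arm_label"))
}

#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(time, survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  title = attr(object, "arm_label"))
}
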