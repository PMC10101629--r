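# Reconstruction of pseudo individual-patient data from digitized
# Kaplan-Meier coordinates and numbers at risk (Guyot-style algorithm).
#
# Within each risk-table interval the number of censorings is iterated until
# the implied number at risk at the start of the next interval matches the
# published one; censor times are spread uniformly (slot midpoints) across
# the interval; events are anchored at the digitized coordinates, with
# fractional event estimates rounded half-to-even and the rounding residual
# carried forward so totals are conserved.

validate_digitized <- function(curve) {
  if (!is.data.frame(curve) || !all(c("time", "survival") %in% names(curve))) {
    abort("digitized curve needs columns `time` and `survival`")
  }
  t <- curve$time
  s <- curve$survival
  if (length(t) < 1) abort("digitized curve is empty")
  if (is.unsorted(t, strictly = TRUE)) {
    abort("digitized times must be strictly increasing")
  }
  if (any(s < 0 | s > 1)) abort("digitized survival must lie in [0, 1]")
  if (any(diff(s) > 1e-12)) {
    k <- which(diff(s) > 1e-12)[1]
    abort(paste0(
      "digitized curve increases between t = ", signif(t[k], 5),
      " and t = ", signif(t[k + 1], 5),
      "; survival must be nonincreasing"
    ))
  }
  # anchor at (0, 1) so the product-limit recursion starts from S = 1
  if (t[1] > 0) {
    tibble(time = c(0, t), survival = c(1, pmin(s, 1)))
  } else {
    tibble(time = t, survival = c(1, pmin(s[-1], 1)))
  }
}

# Allocate integer events along coordinates lo..hi of one risk interval
# (t_start, t_end], given the running KM value at entry and fixed censor
# times; censors are removed from the risk set just before the first
# coordinate they precede. Returns list(d, n_next, S_run, neg).
allocate_interval <- function(t, s, lo, hi, n_start, S_start, cens_times,
                              t_start, t_end) {
  d <- integer(hi - lo + 1)
  n_k <- n_start
  S_run <- S_start
  carry <- 0
  prev_t <- t_start
  for (j in seq_along(lo:hi)) {
    k <- lo + j - 1
    n_k <- n_k - sum(cens_times >= prev_t & cens_times < t[k])
    raw <- if (S_run <= 0 || n_k <= 0) 0 else n_k * (1 - s[k] / S_run) + carry
    dk <- round(raw) # round() is half-to-even
    dk <- max(0L, min(as.integer(dk), n_k))
    carry <- raw - dk
    if (n_k > 0 && dk > 0) S_run <- S_run * (1 - dk / n_k)
    d[j] <- dk
    n_k <- n_k - dk
    prev_t <- t[k]
  }
  n_k <- n_k - sum(cens_times >= prev_t & cens_times < t_end)
  list(d = d, n_next = n_k, S_run = S_run)
}

slot_midpoints <- function(n, from, to) {
  if (n <= 0) return(numeric(0))
  from + (seq_len(n) - 0.5) * (to - from) / n
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Inverts the Kaplan-Meier estimator: given digitized curve coordinates and
#' a numbers-at-risk table, estimates how many events and censorings occurred
#' in each risk interval so that the reconstructed records reproduce both the
#' curve and the risk table.
#'
#' @param curve Data frame with `time` and `survival` columns
#'   ([digitize_curve()] output or a CSV read with those columns).
#' @param risk Data frame with `interval_start` and `n_risk` columns
#'   ([risk_table()] output). The first interval's `n_risk` is the sample
#'   size of the reconstruction.
#' @param total_events Optional published total event count; when given, a
#'   final pass rescales last-interval events so the total matches.
#' @return A `pseudo_ipd` tibble (`time`, `event`) whose row count equals the
#'   initial number at risk. Attribute `diagnostics` holds per-interval event
#'   and censoring counts.
#' @examples
#' arm <- trial_arm_spec("a", "weibull", c(scale = 10, shape = 1.3),
#'                       n_patients = 120, max_followup = 30, seed = 42)
#' ipd <- simulate_arm(arm)
#' km <- km_curve(ipd)
#' dig <- digitize_curve(km, grid = seq(0, 30, by = 0.25))
#' rec <- reconstruct_ipd(dig, risk_table(km, seq(0, 24, by = 6)))
#' nrow(rec) == nrow(ipd)
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  cv <- validate_digitized(curve)
  if (!is.data.frame(risk) ||
      !all(c("interval_start", "n_risk") %in% names(risk))) {
    abort("risk table needs columns `interval_start` and `n_risk`")
  }
  if (any(risk$n_risk < 0) || any(diff(risk$n_risk) > 0)) {
    abort("numbers at risk must be nonnegative and nonincreasing")
  }
  if (risk$n_risk[1] < 1) abort("initial number at risk must be >= 1")
  t <- cv$time
  s <- cv$survival
  K <- length(t)
  trisk <- risk$interval_start
  nrisk <- as.integer(risk$n_risk)
  I <- length(trisk)
  if (max(trisk) > max(t)) {
    abort("digitized curve does not cover every risk interval")
  }
  if (trisk[1] < t[1]) abort("first risk interval starts before the curve")
  # interval i owns coordinates with trisk[i] < t <= trisk[i+1]: the drop
  # recorded at a boundary coordinate happened among the subjects at risk in
  # the preceding interval, which is what the published n at that boundary
  # already reflects
  bounds <- c(trisk, max(t))
  lower <- integer(I)
  upper <- integer(I)
  for (i in seq_len(I)) {
    inside <- which(t > bounds[i] & t <= bounds[i + 1])
    if (length(inside) == 0 && i < I) {
      abort(paste0("no digitized coordinate in risk interval ", i))
    }
    lower[i] <- if (length(inside)) inside[1] else NA_integer_
    upper[i] <- if (length(inside)) inside[length(inside)] else NA_integer_
  }

  d_all <- integer(K)
  cens_all <- vector("list", I)
  n_start <- nrisk[1]
  anchor <- which(t <= trisk[1])
  S_start <- if (length(anchor)) s[anchor[length(anchor)]] else 1
  for (i in seq_len(I)) {
    lo <- lower[i]
    hi <- upper[i]
    if (is.na(lo)) { # empty tail interval: nothing to allocate
      cens_all[[i]] <- numeric(0)
      next
    }
    t_end <- bounds[i + 1]
    if (i < I) {
      # first guess per Guyot, then adjust until the next published n matches
      guess <- round(n_start * s[hi] / max(S_start, 1e-12)) - nrisk[i + 1]
      nc <- max(0L, min(as.integer(guess), n_start))
      tried <- integer(0)
      best <- NULL
      repeat {
        ct <- slot_midpoints(nc, bounds[i], t_end)
        al <- allocate_interval(t, s, lo, hi, n_start, S_start, ct,
                                bounds[i], t_end)
        gap <- al$n_next - nrisk[i + 1]
        if (is.null(best) || abs(gap) < abs(best$gap)) {
          best <- list(nc = nc, ct = ct, al = al, gap = gap)
        }
        if (gap == 0 || nc %in% tried) break
        tried <- c(tried, nc)
        nc <- max(0L, min(nc + gap, n_start))
        if (nc %in% tried) break
      }
      if (best$gap < -(2 + 0.05 * n_start)) {
        abort(paste0(
          "risk table inconsistent with curve in interval ", i,
          " (would imply negative events or censorings)"
        ))
      }
      # a small residual gap (noisy digitization) is tolerated: continue
      # with the computed risk set
      d_all[lo:hi] <- best$al$d
      cens_all[[i]] <- best$ct
      n_start <- best$al$n_next
      S_start <- best$al$S_run
    } else {
      # last interval: no information on censoring; assume none before the
      # final coordinate (administrative censoring afterwards)
      al <- allocate_interval(t, s, lo, hi, n_start, S_start, numeric(0),
                              bounds[i], t_end)
      d_all[lo:hi] <- al$d
      cens_all[[i]] <- numeric(0)
      n_start <- al$n_next
      S_start <- al$S_run
    }
  }

  if (!is.null(total_events) && sum(d_all) != total_events) {
    # reallocation pass toward the published total: trim (or add) events
    # from the tail of the curve backwards, which touches the last interval
    # first and earlier ones only if it must
    excess <- sum(d_all) - as.integer(round(total_events))
    if (excess > 0) {
      for (k in rev(seq_len(K))) {
        if (excess == 0) break
        adj <- min(d_all[k], excess)
        d_all[k] <- d_all[k] - adj
        excess <- excess - adj
        n_start <- n_start + adj
      }
    } else if (excess < 0) {
      add <- min(n_start, -excess) # only untracked survivors can convert
      d_all[K] <- d_all[K] + add
      n_start <- n_start - add
      excess <- excess + add
    }
    if (excess != 0) {
      warn("total_events could not be matched exactly")
    }
    d_all <- as.integer(d_all)
  }

  ev_times <- rep(t, times = d_all)
  cens_times <- unlist(cens_all)
  tail_cens <- rep(max(t), n_start)
  out <- tibble(
    time = c(ev_times, cens_times, tail_cens),
    event = c(
      rep(1L, length(ev_times)),
      rep(0L, length(cens_times) + length(tail_cens))
    )
  )
  out <- out[out$time > 0, , drop = FALSE]
  if (nrow(out) == 0) abort("reconstruction produced no records")
  diag <- tibble(
    interval = seq_len(I),
    interval_start = trisk,
    events = vapply(seq_len(I), function(i) {
      if (is.na(lower[i])) 0L else as.integer(sum(d_all[lower[i]:upper[i]]))
    }, integer(1)),
    censored = vapply(cens_all, length, integer(1))
  )
  new_pseudo_ipd(out, arm_label = attr(curve, "arm_label"),
                 diagnostics = diag)
}

#' Reconstruct pseudo-IPD without a numbers-at-risk table
#'
#' Fallback when a figure prints no risk table: assumes no censoring before
#' the last coordinate and allocates events so the empirical survival tracks
#' the digitized curve. The result carries `approximate = TRUE` metadata.
#'
#' @param curve Data frame with `time` and `survival` columns.
#' @param n_total Number of subjects at time zero (>= 1).
#' @return A `pseudo_ipd` tibble of `n_total` records.
#' @export
reconstruct_without_risk_table <- function(curve, n_total) {
  cv <- validate_digitized(curve)
  if (!is.numeric(n_total) || n_total < 1) abort("n_total must be >= 1")
  n_total <- as.integer(n_total)
  cum_events <- round(n_total * (1 - cv$survival))
  if (max(cum_events) > n_total) {
    abort("n_total is smaller than the number of events the curve implies")
  }
  d <- diff(c(0, cum_events))
  if (any(d < 0)) abort("digitized curve increases; cannot allocate events")
  ev_times <- rep(cv$time, times = d)
  n_left <- n_total - sum(d)
  out <- tibble(
    time = c(ev_times, rep(max(cv$time), n_left)),
    event = c(rep(1L, length(ev_times)), rep(0L, n_left))
  )
  out <- out[out$time > 0, , drop = FALSE]
  new_pseudo_ipd(out, arm_label = attr(curve, "arm_label"),
                 approximate = TRUE)
}

#' Supremum distance between two survival curves
#'
#' Largest absolute difference between two curves evaluated over the union of
#' the given times (right-continuous step evaluation for KM curves).
#'
#' @param a,b Curves accepted by [survival_at()].
#' @param times Evaluation times.
#' @return A single nonnegative number.
#' @export
sup_distance <- function(a, b, times) {
  max(abs(survival_at(a, times) - survival_at(b, times)))
}
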