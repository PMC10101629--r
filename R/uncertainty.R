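# Deterministic (one-way / tornado) and probabilistic sensitivity analysis.
#
# Parameter specifications carry a base value and a low/high range (by
# default +/-20% of base). For PSA the range is converted to a standard
# error with the normal approximation sd = (high - low) / (2 * 1.96), then
# moment-matched: beta for probabilities/utilities, gamma for costs,
# lognormal for hazard ratios (log-sd = (log high - log low) / (2 * 1.96)).

#' Specify one uncertain parameter
#'
#' @param name Parameter name (must match a name the model closure accepts).
#' @param base Base-case value.
#' @param low,high Range for one-way analysis and PSA dispersion; default
#'   +/-20% of base.
#' @param psa_family `"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param role `"utility"`, `"probability"`, `"cost"`, `"hazard-ratio"` or
#'   `"other"` (informational).
#' @return One-row tibble.
#' @export
param_spec <- function(name, base, low = 0.8 * base, high = 1.2 * base,
                       psa_family = c("gamma", "beta", "lognormal", "fixed"),
                       role = "other") {
  psa_family <- match.arg(psa_family)
  if (low > base || base > high) abort(
    paste0("parameter '", name, "': need low <= base <= high")
  )
  if (psa_family == "beta" && (low < 0 || high > 1)) {
    abort(paste0("parameter '", name, "': beta family needs a [0, 1] range"))
  }
  tibble(name = name, base = base, low = low, high = high,
         psa_family = psa_family, role = role)
}

psa_sd <- function(specs) (specs$high - specs$low) / (2 * stats::qnorm(0.975))

draw_one <- function(spec, n) {
  m <- spec$base
  s <- (spec$high - spec$low) / (2 * stats::qnorm(0.975))
  if (spec$psa_family == "fixed" || s == 0) return(rep(m, n))
  switch(spec$psa_family,
    beta = {
      v <- s^2
      if (m <= 0 || m >= 1 || m * (1 - m) <= v) {
        abort(paste0(
          "beta moment matching infeasible for parameter '", spec$name,
          "' (mean ", signif(m, 4), ", sd ", signif(s, 4), ")"
        ))
      }
      a <- m * (m * (1 - m) / v - 1)
      rbeta(n, a, a * (1 - m) / m)
    },
    gamma = {
      v <- s^2
      rgamma(n, shape = m^2 / v, rate = m / v)
    },
    lognormal = {
      sdlog <- (log(spec$high) - log(spec$low)) / (2 * stats::qnorm(0.975))
      rlnorm(n, meanlog = log(m), sdlog = sdlog)
    },
    abort(paste0("unknown psa_family '", spec$psa_family, "'"))
  )
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' @param specs Tibble of [param_spec()] rows.
#' @param n Number of draws.
#' @param seed Optional seed for reproducibility.
#' @return A tibble with `n` rows, one column per parameter.
#' @export
draw_params <- function(specs, n = 1, seed = NULL) {
  do_draw <- function() {
    cols <- lapply(seq_len(nrow(specs)), function(i) draw_one(specs[i, ], n))
    setNames(as_tibble(cols, .name_repair = "minimal"), specs$name)
  }
  if (is.null(seed)) do_draw() else withr::with_seed(seed, do_draw())
}

pair_icer <- function(results, pair) {
  a <- results[results$strategy == pair[1], ]
  b <- results[results$strategy == pair[2], ]
  if (nrow(a) != 1 || nrow(b) != 1) {
    abort("comparator pair not found in model results")
  }
  (a$cost - b$cost) / (a$qaly - b$qaly)
}

#' One-way sensitivity of an ICER to a single parameter
#'
#' Re-evaluates the model twice with the parameter pinned at its low and
#' high value (all other parameters at base) and reports the resulting
#' ICERs for the given strategy pair.
#'
#' @param specs Tibble of [param_spec()] rows; `param` must appear in it.
#' @param param Parameter name to vary.
#' @param model A model closure as returned by [build_ce_model()]: a
#'   function taking a named vector of parameter overrides and returning a
#'   tibble with `strategy`, `cost`, `qaly`.
#' @param pair Character vector `c(strategy, comparator)`.
#' @return One-row tibble: `parameter`, `icer_low`, `icer_high`, `width`.
#' @export
one_way <- function(specs, param, model, pair) {
  row <- specs[specs$name == param, ]
  if (nrow(row) != 1) abort(paste0("unknown parameter '", param, "'"))
  icer_lo <- pair_icer(model(setNames(row$low, param)), pair)
  icer_hi <- pair_icer(model(setNames(row$high, param)), pair)
  tibble(parameter = param, icer_low = icer_lo, icer_high = icer_hi,
         width = abs(icer_hi - icer_lo))
}

#' Tornado analysis
#'
#' Runs [one_way()] for every parameter and ranks them by the width of the
#' ICER excursion, widest first.
#'
#' @inheritParams one_way
#' @return A tibble of class `tornado` sorted by decreasing `width`, with
#'   the base-case ICER in attribute `icer_base`.
#' @export
tornado <- function(specs, model, pair) {
  if (nrow(specs) < 1) abort("tornado needs at least one parameter")
  rows <- purrr::map(specs$name, function(p) one_way(specs, p, model, pair))
  out <- dplyr::arrange(purrr::list_rbind(rows), dplyr::desc(width))
  out <- structure(out, class = c("tornado", class(out)))
  attr(out, "icer_base") <- pair_icer(model(NULL), pair)
  attr(out, "pair") <- pair
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iter` parameter sets from the PSA distributions and re-evaluates
#' the model for each, retaining per-iteration discounted cost and QALYs per
#' strategy. Iterations violating model preconditions are recorded as
#' failed; the run aborts if more than 1% fail.
#'
#' @param model Model closure from [build_ce_model()].
#' @param specs Tibble of [param_spec()] rows.
#' @param n_iter Number of Monte Carlo iterations (published analysis:
#'   10,000).
#' @param seed Seed for reproducibility.
#' @return A `psa_run` list: `results` (tibble `iteration`, `strategy`,
#'   `cost`, `qaly`), `samples` (the drawn parameters), `n_iter`, `seed`,
#'   `n_failed`.
#' @export
run_psa <- function(model, specs, n_iter = 10000, seed = NULL) {
  if (n_iter < 1) abort("n_iter must be >= 1")
  samples <- draw_params(specs, n = n_iter, seed = seed)
  sample_mat <- as.matrix(samples)
  res <- vector("list", n_iter)
  failed <- logical(n_iter)
  for (i in seq_len(n_iter)) {
    r <- tryCatch(model(sample_mat[i, ]), error = function(e) NULL)
    if (is.null(r)) {
      failed[i] <- TRUE
    } else {
      r$iteration <- i
      res[[i]] <- r
    }
  }
  if (mean(failed) > 0.01) {
    abort(paste0(sum(failed), " of ", n_iter,
                 " PSA iterations failed model preconditions (> 1%)"))
  }
  results <- purrr::list_rbind(res[!failed])
  structure(
    list(
      results = results[, c("iteration", "strategy", "cost", "qaly")],
      samples = samples, n_iter = n_iter, seed = seed,
      n_failed = sum(failed)
    ),
    class = "psa_run"
  )
}

#' @export
print.psa_run <- function(x, ...) {
  cat("<psa_run> ", x$n_iter, " iterations, ",
      length(unique(x$results$strategy)), " strategies",
      if (x$n_failed > 0) paste0(" (", x$n_failed, " failed)"), "\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, each strategy's acceptability is the
#' fraction of PSA iterations in which it attains the strictly highest net
#' monetary benefit; exact ties split the iteration equally among the tied
#' strategies, so probabilities sum to 1 at every threshold.
#'
#' @param run A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay values (USD/QALY, nonempty).
#' @return A tibble of class `ceac`: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(run, wtp_grid) {
  if (length(wtp_grid) == 0) abort("empty willingness-to-pay grid")
  if (nrow(run$results) == 0) abort("PSA run holds no results")
  wide_c <- tidyr::pivot_wider(run$results, id_cols = iteration,
                               names_from = strategy, values_from = cost)
  wide_q <- tidyr::pivot_wider(run$results, id_cols = iteration,
                               names_from = strategy, values_from = qaly)
  strategies <- setdiff(names(wide_c), "iteration")
  C <- as.matrix(wide_c[, strategies])
  Q <- as.matrix(wide_q[, strategies])
  out <- purrr::map(wtp_grid, function(w) {
    nmb <- w * Q - C
    best <- matrixStats_rowMaxs(nmb)
    win <- nmb >= best - 1e-9 # ties within numerical noise share the win
    share <- win / rowSums(win)
    tibble(wtp = w, strategy = strategies,
           probability = unname(colMeans(share)))
  })
  out <- purrr::list_rbind(out)
  structure(out, class = c("ceac", class(out)))
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' @export
autoplot.ceac <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(wtp, probability, colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective", colour = NULL)
}

#' @export
autoplot.tornado <- function(object, ...) {
  base <- attr(object, "icer_base")
  df <- dplyr::mutate(object,
                      parameter = factor(parameter, levels = rev(parameter)))
  ggplot2::ggplot(df, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_low, xend = icer_high,
                                       yend = parameter), linewidth = 4) +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL)
}

#' @export
autoplot.psa_run <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(qaly, cost, colour = strategy)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::labs(x = "QALYs", y = "Cost (USD)", colour = NULL)
}
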