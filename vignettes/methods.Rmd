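---
title: "Methods: from digitized survival curves to cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from digitized survival curves to cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmce)
```

## The decision problem

Nine first-line systemic regimens for unresectable advanced hepatocellular
carcinoma — six oral multikinase inhibitors, two immune-checkpoint-inhibitor
combinations, and the sorafenib reference — are compared on discounted
lifetime cost, life-years and QALYs from a payer perspective. Because the
evidence base is published trial figures rather than patient-level data, the
pipeline starts from digitized Kaplan–Meier coordinates and rebuilds
everything downstream from them.

## Pipeline and assumptions

### 1. Curve reconstruction (Guyot inversion)

Digitized coordinates $(t_k, S_k)$ and numbers at risk $n_i$ at interval
starts are inverted into pseudo individual-patient records. Within each
risk interval the number of censorings is iterated until the implied number
at risk at the next interval start matches the published one; censor times
sit at the midpoints of equal slots across the interval (the uniform-
censoring assumption); events are anchored at the digitized coordinates.
Fractional event estimates are rounded half-to-even with the residual
carried to the next coordinate, so interval totals are conserved.

Two conventions matter and are fixed here:

* **Boundary attribution.** Interval $i$ owns coordinates with
  $t_{i} < t \le t_{i+1}$. The published number at risk at a boundary time
  already reflects every drop up to that time, so the drop recorded *at*
  the boundary coordinate is allocated among the subjects of the preceding
  interval. With jitter-free digitization on a grid denser than the event
  times, this convention recovers the generating event count of every
  interval exactly (a tested property).
* **Last interval.** No information constrains censoring there; we assume
  none before the final coordinate and censor all remaining subjects
  administratively at the last time. When a published total event count is
  supplied, a reallocation pass trims or adds events from the tail until
  the total matches.

A fallback without any risk table (`reconstruct_without_risk_table()`)
assumes no censoring before the last coordinate and is flagged
`approximate` in its metadata.

### 2. Parametric fitting and selection

Five families are fitted by right-censored maximum likelihood,
$\ell = \sum_{events}\log h(t_i) + \sum_{all}\log S(t_i)$, with these
parameterizations (stated once, used everywhere — cross-package
parameterization drift is the main reproducibility hazard in this area):

| family | survival function | parameters |
|---|---|---|
| exponential | $e^{-\lambda t}$ | `rate` |
| Weibull | $\exp(-(t/\alpha)^\beta)$ | `scale`, `shape` |
| log-logistic | $1/(1+(t/\alpha)^\beta)$ | `scale` (= median), `shape` |
| log-normal | $1-\Phi((\log t-\mu)/\sigma)$ | `meanlog`, `sdlog` |
| Gompertz | $\exp(-\frac{\lambda}{\gamma}(e^{\gamma t}-1))$ | `rate`, `shape` |

Optimization runs on log-transformed parameters (positivity by
construction; the log-normal `meanlog` stays on the real line) with
Nelder–Mead from three moment-based starts plus a polishing pass;
the one-parameter exponential uses golden-section search at tolerance
1e-10 so the numerical optimum matches the closed form $d/\sum t_i$ to
1e-6 relative. Constraining the Gompertz shape to be positive is a design
choice (all parameters positive); data with decreasing hazard simply make
another family win the AIC. Selection is minimum AIC $=2k-2\log L$; exact
ties go to fewer parameters, then to the fixed family order exponential,
Weibull, log-logistic, log-normal, Gompertz. Selection is re-run per
endpoint on the user's data; a message notes when the winner differs from
the log-logistic family chosen in the reference analysis.

Comparator arms are derived by proportional hazards,
$S_{adj}(t)=S_{base}(t)^{HR}$, with one hazard ratio per endpoint (PFS and
OS) per strategy. Whether the original analysis applied its
network-meta-analysis HRs to one endpoint or both is not stated; treating
them as per-endpoint configuration is the more general reading and the
package's default.

### 3. Cohort engine

State occupancies are read directly off the curves each cycle —
$\mathrm{PFS}=S_{pfs}(t_k)$, $\mathrm{PD}=\max(S_{os}-S_{pfs},0)$,
$\mathrm{Death}=1-S_{os}$ — the partitioned-survival construction that the
curve-difference description of the model prescribes, even though such
models are conventionally called Markov models. A per-cycle transition-
matrix view is available for inspection (`trace_transitions()`), but the
trace is authoritative. Where noise or HR adjustment makes
$S_{os}<S_{pfs}$, PD is clamped at zero, PFS is capped at $S_{os}$ so rows
still sum to 1, and the clamped mass is reported.

Timing conventions: cycles are stamped at their starts,
$t_k = k \times 21$ days; membership and discounting,
$(1+r)^{-t_k/365.25}$ with $r=0.05$/year, are evaluated there, cycle 0
undiscounted. The cycle count is
$\lceil 10 \times 365.25 / 21 \rceil = 174$. A half-cycle-correction flag
(default off, since the source analysis is silent) halves the first and
last cycle contributions; with state occupancies changing by at most one
cycle of mass, it moves totals by less than one cycle's worth — a tested
bound.

### 4. Costs, utilities, decision statistics

* Drug costs are per-mg linear (no vial wastage model — vial sizes are not
  published). Daily dosing accrues `admin_per_day × 21` administrations a
  cycle; every-$k$-weeks dosing accrues $21/7k$ — i.e. q3w = 1, q2w = 1.5
  administrations per 21-day cycle, a continuous-rate approximation rather
  than calendar simulation.
* Per-kg doses use a 60 kg baseline weight. Lenvatinib defaults to
  8 mg/day (the source's stated base case) with the published
  weight-threshold rule (8 mg under 60 kg, 12 mg at or above) available as
  an option.
* Second-line camrelizumab (200 mg q2w) + apatinib (250 mg daily) cost
  accrues for the whole progressed-state occupancy, uncapped by default
  (no stopping rule is published); a cycle cap is configurable because
  one-way sensitivity shows second-line price is influential.
* Grade ≥3 adverse events enter once at model entry as incidence-weighted
  expected cost and expected QALY decrement — the one-off-decrement
  treatment, since no duration data exist.
* Utilities: PFS 0.760, PD 0.680. Testing costs apply in both alive states
  by default (configurable; the original is silent).
* ICERs are reported against the reference; a comparator that is cheaper
  and more effective is flagged dominant rather than given a negative
  ICER. The frontier removes strict dominance first, then extended
  dominance by the non-monotone-sequential-ICER rule; exactly equal
  sequential ICERs retain the middle strategy.
* The willingness-to-pay default is $37,654.50/QALY (three times 2021
  GDP per capita); the same source elsewhere prints $38,498.89, so the
  threshold is configuration, not a constant.

### 5. Uncertainty

One-way analysis pins one parameter at ±20% of base (all else at base) and
re-evaluates the full model; the tornado ranks parameters by the width of
the ICER excursion. For the PSA, ranges become distributions by the
normal-approximation standard error $sd=(high-low)/(2\times1.96)$, moment-
matched to beta (probabilities, utilities), gamma (costs) or lognormal
(hazard ratios, log-sd from the log range). How the original converted its
±20% ranges into distribution parameters is unstated; this convention is
the common one and is declared here once. Acceptability curves report, at
each willingness-to-pay value, the fraction of iterations in which each
strategy attains the highest net monetary benefit, exact ties splitting
the iteration equally — so the probabilities sum to one by construction.
Baseline-curve parameter uncertainty is *not* propagated by default (only
probability, cost and HR distributions are named in the source); drawing
survival parameters would be an extension.

All randomness flows from a single root seed split per stage, making the
whole pipeline bit-reproducible.

## The synthetic world

No supplementary input tables are machine-readable, so the package ships a
stated synthetic configuration (`make_model_inputs()`):

* Reference (sorafenib) PFS and OS arms are log-logistic with medians 5.5
  and 10.7 months — SHARP-like values — and a shared shape of 1.5, which
  makes $S_{pfs}\le S_{os}$ hold analytically at every time (with unequal
  shapes the curves would cross near zero). 450 patients, administrative
  censoring at 24/36 months, monthly digitization grid with jitter
  standard deviation 0.005 on the probability scale, risk tables every 3
  months.
* Dosing follows the published regimen table; per-mg prices, NMA hazard
  ratios and adverse-event profiles are synthetic stand-ins chosen once
  for a realistic ordering (reference cheapest, ICI combinations most
  expensive). They are not the unpublished originals, so absolute totals
  will not and should not reproduce the published ones.

What a green test therefore establishes: the *machinery* — reconstruction
fidelity, likelihood maximization, AIC selection frequencies, trace
conservation, discounting, dominance logic, PSA calibration — behaves
correctly on data with the assumed structure. What it does not establish:
agreement with the published absolute costs and QALYs (those depend on the
unpublished supplementary inputs), nor robustness to digitization
pathologies a real figure might show (plateau artifacts, mis-read risk
tables, informative censoring).

## Numerical choices

* Digitized curves are forced nonincreasing by a running minimum anchored
  at $S=1$ (isotonic clipping); zero-jitter digitization is exactly the
  curve on the grid.
* Small inconsistencies between a noisy curve and its risk table are
  tolerated (the iteration keeps the best-matching censor count); an
  implied shortfall greater than $2 + 0.05\,n$ subjects is treated as a
  genuinely inconsistent input and errors, naming the interval.
* The PD-clamp diagnostic accumulates the total clamped occupancy mass per
  strategy and is written to the run log.
* PSA iterations that violate model preconditions are recorded as failed;
  a run aborts if more than 1% fail.
* The model closure used by the sensitivity analyses shares its
  accumulation kernel with the public `accumulate_ce()` route, so the two
  paths agree exactly (a tested identity rather than an approximation).

## Known limitations

* No spline or cure models; no joint PFS–OS modelling; no tunnel states or
  time-varying utilities; no microsimulation.
* The one-off adverse-event treatment understates burdens that persist.
* Proportional hazards is assumed wherever an HR is applied; crossing
  hazards would need strategy-specific curves instead (the configuration
  accepts per-strategy digitized curves for that case).
* Currency conversion and inflation adjustment are out of scope: prices
  enter the configuration already in analysis-year USD.
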