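---
title: "Surgical demand and time to hip fracture surgery: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surgical demand and time to hip fracture surgery: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hipwait)
```

hipwait studies a health-services question: when a patient with a hip
fracture arrives at a hospital, how much longer do they wait for surgery
because of the *demand* already present — the other hip-fracture patients
ahead of them in the queue — rather than because of their own clinical
condition? The package implements the full analysis chain on hospital
discharge abstracts: episode-of-care assembly, a queueing-based demand
metric, an interval-censored log-normal accelerated failure time (AFT) model
with hospital random effects and cluster-robust errors, and a nonparametric
estimator of the cumulative probability of surgery. Because real discharge
abstracts are confidential, the package also contains a first-class
discrete-event generator of synthetic abstracts with known, configurable
demand effects, so that every stage is testable end to end.

## The clearance-time demand metric

Demand at admission is summarized by the *clearance time*: the expected
number of days needed for every hip-fracture patient hospitalized and still
awaiting surgery to be operated on, were the hospital to work at its maximum
service rate with no new arrivals. With census $Q$ (preoperative
hip-fracture patients present on the admission day, the index patient
included) and maximum weekly service rate $S$ (the largest number of hip
fracture surgeries the hospital performed in any single week of the fiscal
quarter),

$$C = \frac{Q}{S/7} \quad \text{days}.$$

Four categories partition $C$: *benchmark* demand clears within the 2-day
national benchmark ($C \le 2$), *medium* within 4, *high* within 6, and
*excessive* demand needs 7 or more days ($C > 6$). Three conventions here
are genuinely open and are therefore explicit options with documented
defaults:

* **Weeks within a quarter.** "A single week" is operationalized as
  consecutive 7-day blocks anchored at the fiscal quarter's first day
  (Canadian fiscal year, Q1 = April–June). Anchored blocks are reproducible
  and do not inflate the maximum through sliding windows; the final partial
  block still counts, which can only lower the maximum it contributes.
* **The index patient.** They are part of the demand present on their own
  admission day, so they count in $Q$ by default
  (`include_index = TRUE` in `assess_demand()`).
* **Boundaries.** Categories are closed on the right ($C = 2$ is still
  benchmark), matching the "within 2 days" phrasing; with integer censuses
  and rates, $C > 6$ coincides with needing at least 7 whole days, and a
  `ceiling_days` option classifies $\lceil C \rceil$ instead for users who
  prefer the whole-days reading. The two conventions agree everywhere except
  exactly on the boundary arithmetic, which the test suite checks against a
  day-by-day queue-drain oracle.

The rate used for an episode is that of the admission hospital in the fiscal
quarter containing the admission date.

## Censoring intervals and the AFT model

Discharge data record the *inpatient day* of surgery, not the hour. Surgery
on inpatient day $N$ therefore locates the waiting time in the interval
$(N-1, N]$ days. Day 1 yields a left-censored observation at 1 day (the log
of the zero lower bound is unbounded below, so the faithful likelihood term
is $\Phi(\cdot)$, not a difference), and surgeries after 7 inpatient days
are right-censored at 7 — delays that long are attributed to medical
instability rather than to demand, and the horizon is configurable
(`build_intervals(horizon = )`).

On the log scale the model is a log-normal AFT with hospital random effects:
for episode $i$ in hospital $h$,

$$\log T_{ih} \sim \mathcal{N}\!\left(x_{ih}'\beta + b_{0h} + b_{1h}\,s_{ih},\; \sigma^2\right),
\qquad b_{0h} \sim \mathcal{N}(0, \tau_0^2),\; b_{1h} \sim \mathcal{N}(0, \tau_1^2),$$

where $x_{ih}$ contains indicators for the three non-reference demand
categories and the adjustment covariates, and $s_{ih} \in \{0,1,2,3\}$ is an
ordinal demand score. Each hospital's marginal likelihood integrates the
product of interval probabilities
$\Phi\!\big(\tfrac{\log U - \eta}{\sigma}\big) - \Phi\!\big(\tfrac{\log L - \eta}{\sigma}\big)$
over the random effects.

**Why an ordinal random slope?** "Letting the effect of demand vary by
hospital" admits several designs. A separate random slope per category would
need 4-dimensional integration, which is numerically impractical and hard to
identify with moderate hospital counts; the default instead pairs the fixed
category indicators (which carry the estimand) with a single random slope on
the ordinal score (which carries the between-hospital heterogeneity in the
demand *gradient*). This keeps the integral two-dimensional, and the random
structure is configurable (`random = "none" / "intercept" /
"intercept_slope"`).

**Numerics.** The integral uses adaptive Gauss–Hermite quadrature: per
hospital, the posterior mode of the random effects is located by damped
Newton steps with analytic first and second derivatives (the censored
log-normal log-likelihood is concave in the linear predictor, so the inner
problem is globally well behaved), the quadrature grid is centred and scaled
by the mode and curvature, and 9 nodes per dimension is the default
(`nodes =`); the likelihood changes by less than $10^{-6}$ between 9 and 15
nodes on test problems, and the heavier computations in the package's own
scripts use 5 nodes, which agrees with 15 to ~$10^{-8}$ on day-grid data.
Optimization is BFGS on the unconstrained vector
$(\beta, \log\sigma, \log\tau_0, \log\tau_1)$; convergence is reported with
the gradient norm, and coefficients with $|\beta| > 10$ on the log-day scale
abort with a separation diagnosis. When $\tau_1 \to 0$ the profile in
$\log\tau_1$ flattens and the observed information can become singular; the
covariance then falls back to a symmetric pseudo-inverse with a warning,
which leaves the $\beta$ block unaffected.

**Inference.** Standard errors default to the clustered sandwich
$A^{-1} B A^{-1}$, with $A$ the observed information and $B$ the
outer-product sum of per-hospital score vectors (numerical derivatives of
the per-hospital marginal log-likelihood), scaled by the small-sample factor
$G/(G-1)$. Effects are reported as percent changes in the median,
$(\mathrm{e}^{\beta_k} - 1)\times 100\%$, with Wald limits transformed from
the coefficient scale; the identity
$\text{median ratio} - 1 = \mathrm{e}^{\beta_k} - 1$ holds exactly for every
fit and is asserted in the tests. Group medians come from the demand-only
model; *adjusted* medians are evaluated at the cohort's modal covariate
profile (`modal_profile()`), since a single representative profile keeps the
median on the day scale interpretable — marginalizing over the covariate
distribution is a reasonable alternative the package does not implement.

## The Turnbull curves

Cumulative probabilities of surgery within $t$ days are estimated
nonparametrically from the same censoring intervals by self-consistency EM
on the Turnbull support intervals. On a day grid the supports are the days
themselves, every valid interval-censored NPMLE coincides there, and the
estimator reduces to the ECDF on exact data and to the product-limit
estimator under pure right censoring (both asserted at $10^{-8}$). The EM
stops when the largest mass change falls below $10^{-8}$ (configurable); the
log-likelihood trace is stored and its monotonicity asserted in tests. The
CDF is right-continuous and evaluated at integer days; strictly inside a
support interval the NPMLE is undefined and evaluation returns `NA` with the
interval reported.

## The synthetic cohort generator

`sim_cohort()` emulates the statistical structure the analysis assumes,
not any real hospital system:

* **Arrivals** are homogeneous Poisson per hospital-day; weekend admissions
  arise from the calendar, weekday AM/PM timing from a frequency table.
* **Capacity** is laid out as daily surgical slots summing to a weekly
  total `round(base × quarter multiplier × hospital size factor)`, the size
  factor log-normal so that bigger hospitals have both more arrivals and
  more capacity.
* **Outcomes**: each patient receives a latent log waiting time — baseline
  plus the true effect of the demand category realized at admission, plus
  hospital random effects and Normal noise; patients flagged with a medical
  reason for delay are additionally held for a log-normal stabilization
  time. The patient becomes eligible on inpatient day `ceiling(latent)` and
  is scheduled first-in-first-out among eligible patients within the day's
  slots. FIFO is an assumption of the generator only; the data do not reveal
  the discipline real hospitals used.
* **Abstract splitting**: a configurable fraction of episodes is emitted as
  two abstracts with contiguous dates (a preoperative transfer from a
  random referring hospital), so the merge rule is exercised; the ground
  truth table is retained for testing.

Defaults were calibrated once against published cohort summaries: baseline
median 1.5 days with $\sigma = 0.6$ (putting roughly 68/94/98% of
benchmark-demand surgeries within 2/4/7 days), true demand effects
$+5.1/+12.2/+22.0\%$, 6.7% medical-delay prevalence with a median 0.7-day
hold, an 8.6% transfer fraction, arrivals of 0.52/day per hospital
(≈190/year), and covariate tables matching the published marginal
distributions. The full-size default (89 hospitals, 2004–2012) approximates
the real cohort's scale; tests and the acceptance script run deliberately
scaled-down systems (5–30 hospitals, 1–2 years, about 1,000–11,000
episodes), stated here as the package's chosen problem sizes.

**What the generator does and does not emulate.** Because scheduling is
capacity-limited, congestion adds a *mechanical* delay on top of the
injected log-time effects: patients admitted at high demand wait longer than
their latent time whenever slots are exhausted. End-to-end estimates on
generator output therefore exceed the injected percent changes — that is a
real feature of the simulated world, not an estimation bias, and it is why
parameter-recovery experiments use `sim_interval_data()`, which draws
day-grid interval observations directly from the fitted model's own data
model (there the recovery study shows the estimator unbiased with near-nominal
CI coverage). The generator also omits features of real discharge data:
competing non-hip-fracture surgical demand, seasonal and secular arrival
trends, miscoded dates, inter-provincial referral patterns, and any
clinical-outcome processes. Passing tests on synthetic data therefore
validate the *pipeline*, not epidemiological conclusions about any real
system.

## Degenerate inputs and edge conventions

* Same-patient abstracts merge when the next admission is on, or one day
  after, the earlier discharge; the exact transfer rule text is not public,
  and the ≤1-day gap is a documented assumption. Overlapping non-contiguous
  stays are kept separate with a warning.
* Annual hospital volume for the ≤24-surgeries exclusion is counted per
  calendar year at the hospital of surgery — the simplest auditable reading
  of "annual volume".
* Hospital-quarters with no surgeries have no defined service rate;
  episodes admitted there are dropped from the demand assessment with a
  logged count.
* Episodes with no surgery date and a stay within the censoring horizon
  carry no information about the waiting-time distribution and are dropped;
  longer surgery-free stays are right-censored at the horizon.
* `lower == upper` marks an exactly observed time (used by the OLS-limit
  tests); `lower <= 0` left censoring; `upper = Inf` right censoring.

## Known limitations

Waiting times are resolved in whole days; effects operating at the scale of
hours are invisible and estimates are attenuated accordingly. The random
slope uses one ordinal score rather than per-category slopes. The sandwich
estimator treats hospitals as independent clusters; shared regional shocks
would violate that. The NPMLE is reported without confidence bands.
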