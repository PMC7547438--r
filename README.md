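# hipwait

Does the backlog of hip-fracture patients already awaiting surgery delay the
next patient who arrives? `hipwait` implements the full analysis chain for
that question on hospital discharge abstracts, for health-services
researchers working with administrative data: episode-of-care assembly from
transfer abstracts, a queueing-based demand metric, an interval-censored
log-normal accelerated failure time (AFT) model with hospital random effects
and cluster-robust errors, and a Turnbull estimator of the cumulative
probability of surgery. Because real discharge abstracts are confidential,
the package ships a discrete-event generator of synthetic abstracts with
known demand effects, so every stage is testable without any data access.

## The model in brief

Demand at admission is the **clearance time** `C = Q / (S/7)`: the days
needed for the `Q` preoperative hip-fracture patients present in hospital to
be operated at the hospital's maximum weekly service rate `S` (the largest
number of surgeries it performed in any week of the fiscal quarter), with no
new arrivals. `C ≤ 2` is benchmark demand, `≤ 4` medium, `≤ 6` high, `> 6`
excessive.

Surgery on inpatient day `N` places the waiting time in `(N−1, N]` days
(left-censored at 1 for day-1 surgery, right-censored at 7 days). On the log
scale:

    log T_ih ~ Normal( x_ih' β + b_0h + b_1h s_ih , σ² ),
    b_0h ~ N(0, τ0²),  b_1h ~ N(0, τ1²),

with demand-category indicators and adjustment covariates in `x`, an ordinal
demand score `s ∈ {0,1,2,3}` carrying the random slope, hospitals `h` as
clusters. Random effects are integrated by adaptive Gauss–Hermite
quadrature; standard errors use the clustered sandwich `A⁻¹ B A⁻¹` with a
`G/(G−1)` correction. A coefficient `β_k` is reported as the percent change
in median time to surgery, `(exp(β_k) − 1)·100%`.

## Worked example

```r
library(hipwait)

cfg <- sim_config(n_hospitals = 8, start_date = "2004-01-01",
                  end_date = "2005-12-31", seed = 42)
res <- run_pipeline(config = cfg, nodes = 5, subgroup_adjusted = FALSE)

dplyr::select(res$table_results[res$table_results$subgroup == "overall", ],
              demand, n, median_days, unadj_pct, adj_pct)
```

```
# A tibble: 4 x 5
  demand        n median_days unadj_pct adj_pct
  <chr>     <int>       <dbl>     <dbl>   <dbl>
1 benchmark  1345        1.60       0       0
2 medium     1569        2.10      30.9    29.7
3 high        408        2.91      81.5    80.7
4 excessive    38        4.50     181.    174.
```

Each row is a demand category: `n` episodes admitted at that level, the
median time to surgery in days from the demand-only model, and the percent
change in the median versus benchmark demand, unadjusted and adjusted for
the standard covariate set. In this simulated system admissions during
excessive demand wait substantially longer than the injected +22% — the
capacity-limited queue adds a mechanical delay on top of the configured
effects (see the methods vignette).

```r
res$curves[res$curves$t %in% c(2, 4, 7) & res$curves$demand == "benchmark", ]
```

```
# A tibble: 3 x 4
  demand        t   cdf     n
  <fct>     <int> <dbl> <int>
1 benchmark     2 0.668  1345
2 benchmark     4 0.940  1345
3 benchmark     7 0.991  1345
```

These are Turnbull estimates of the probability of undergoing surgery within
2, 4 and 7 days of admission for benchmark-demand episodes — about
two-thirds within the 2-day benchmark, matching the generator's calibrated
baseline.

Individual stages are ordinary data-frame functions that chain with the
pipe: `sim_cohort()`, `merge_episodes()`, `apply_exclusions()`,
`assess_demand()`, `build_intervals()`, `aft_intreg()` (with broom-style
`tidy()`/`glance()`), `fit_npmle()`, `surgery_curves()`,
`plot_surgery_curves()`. A thin command-line wrapper lives in
`inst/scripts/run-pipeline.R`.

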