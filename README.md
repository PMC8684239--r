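# extrapsim

Monte Carlo machinery for asking a question that matters to health
technology assessment (HTA): **how wrong can a parametric survival
extrapolation be when the trial behind it is small or stopped early?**

Decision models extrapolate trial time-to-event data to lifetime horizons
to estimate mean survival (life-years). When samples are small (30–120
patients, common in oncology) or follow-up is short (few events observed),
the fitted curve — and everything downstream of it — may be far from the
truth even when the model family is exactly right. `extrapsim` simulates
this situation end to end and quantifies the damage.

## What it does

The package implements a full ADEMP-style simulation study:

1. **Data generation.** A population of *k* = 50,000 individuals with
   staggered trial accrual — enrollment times *t₁ₖ* ~ Uniform(1, *T₁*) days
   — and event times *t₂ₖ* ~ Exponential(λ) from enrollment. Bundled
   scenarios cross accrual length (*T₁* = 270 or 900 days) with hazard
   (λ = 0.0025 or 0.00075 per day).
2. **Sampling and censoring.** For each repetition, samples of
   *n* ∈ {30, 60, 90, 120, 250, 500} are drawn; each sample is then
   administratively censored at the calendar time by which each decile of
   its events (*pₑ* = 10%, …, 100%) has occurred, giving ten nested
   follow-up levels per sample ("groupings"). The clock resets at
   enrollment for analysis.
3. **Fitting.** Six standard parametric families — exponential, Weibull,
   log-normal, log-logistic, generalized gamma (Prentice), Gompertz — fitted
   by right-censored maximum likelihood on the unconstrained parameter
   scale.
4. **Screening and selection.** Fits that fail to converge, do not produce
   descending survival, have 95% CIs spanning > 0.80 survival probability
   at the first event time, yield infinite estimators/CI bounds, or put
   the median beyond the population's maximum event time are removed; the
   best-fitting remaining family is selected by AIC, BIC (and optionally
   AICc/BICc), alongside the correctly-specified exponential analysis.
5. **Estimands and performance.** Median survival (−ln 0.5/λ), one-year
   survival S(365), lifetime time horizon TH (the 1% survival time,
   −ln 0.01/λ), and restricted mean survival time
   RMST(T) = ∫₀ᵀ S(t) dt at both the population horizon and the model's
   own horizon — scored against the population truth by coverage, MAE,
   MAPE, RMSE and the probability of > 20% error, each with Monte Carlo
   standard errors.

## Worked example

```r
library(extrapsim)

cfg <- scenario_preset(1, n_sim = 50, seed = 42)  # desk-scale demo
run <- run_scenario(cfg, criteria = c("aic", "bic"))
print(run)
#> Scenario run: 3000 datasets, 18000 fits attempted
#>   nonconverged: 65 ; implausible: 1940 (11.1% of fits)
#>   criteria: aic, bic, true_family ; truth: population_fit
#>   wall time: 101.9 s

summarize_performance(run, criterion = "bic", estimand = "median",
                      n_obs = c(30, 500), pe = c(0.1, 1))
#>   n_obs  pe n_reps_used  mape mcse_mape prob_20pct_error
#> 1    30 0.1          50 39.34     3.447             0.70
#> 2    30 1.0          50 18.61     1.861             0.44
#> 3   500 0.1          50 10.34     1.255             0.14
#> 4   500 1.0          50  2.97     0.304             0.00
```

Reading the table: with 30 patients and only 10% of events observed, the
BIC-selected model's median survival is off by ~39% on average and misses
the truth by more than 20% in 70% of trials; 500 patients with complete
follow-up bring the average error down to ~3%. Selection quality can be
read off `run$selections` — in this demo BIC picks the true exponential in
91.9% of grouping-repetitions on average.

A command-line wrapper with `simulate` / `run` / `summarize` verbs lives at
`inst/scripts/extrapsim.R`; scenario configurations are YAML files (four
presets under `inst/extdata/`).

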