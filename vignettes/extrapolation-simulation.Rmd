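---
title: "Simulating the performance of parametric survival extrapolation under limited data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the performance of parametric survival extrapolation under limited data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Health decision models routinely extrapolate trial time-to-event data to a
lifetime horizon: a parametric survival curve is fitted to the observed
(right-censored) data, projected forward until essentially all patients
have died, and integrated to obtain mean survival — the life-years that
drive cost-effectiveness results. `extrapsim` quantifies how reliable that
chain is when the trial is small or analyzed early, by simulation from a
known data-generating process.

## The data-generating model

Each simulated population contains `pop_size` individuals (default 50,000)
with two independent draws per individual:

* an **enrollment time** from study start, uniform on [1, `T1`] days,
  mimicking staggered accrual over a recruitment window;
* an **event time** from enrollment, exponential with constant hazard
  `lambda12` per day.

The exponential choice makes the truth exactly known: median = −ln(0.5)/λ,
1% survival time TH = −ln(0.01)/λ, RMST to TH = 0.99/λ. A constant hazard
also isolates the limited-data effects of interest from any misspecification
of hazard shape — with the important caveat (see Limitations) that real
disease processes often have non-constant hazards.

Four bundled scenarios cross accrual with hazard: `T1` = 270 or 900 days
(9 or 30 "months" at the package's 1 month = 30 days convention — the
calendar convention is a package choice, configurable, since hazards are
specified per day) and λ = 0.0025 or 0.00075 per day (medians of roughly
277 and 924 days).

## Samples, follow-up, and the grouping grid

For each of `n_sim` repetitions, one sample per sample-size level
(default {30, 60, 90, 120, 250, 500}) is drawn without replacement from the
population. Follow-up is then manipulated *within* the sample: for each
event proportion `p_e` in {10%, …, 100%}, the calendar time of the
⌈`p_e`·n⌉-th event (enrollment + event time, ties broken by stable sort) is
found, and the sample is administratively censored there — individuals not
yet enrolled at that calendar time are excluded entirely, individuals whose
event falls after it are censored at (censor time − enrollment), and the
clock is reset at enrollment for analysis. Every follow-up level of a
sample is therefore a truncation of the *same* underlying data, so
increasing `p_e` never shortens any individual's observation, and `p_e` = 1
reproduces the complete sample.

Two consequences worth noting. First, at low `p_e` the analyzable sample
can be smaller than n (analysis before full accrual), as happens in
event-driven interim analyses. Second, the ceiling rank means the event
count at `p_e` equals ⌈`p_e`·n⌉ exactly whenever all sampled individuals
are enrolled before the censor time.

Each repetition draws all of its randomness from its own substream seed,
derived from the master seed by a fixed multiplicative-congruential hash.
This makes runs fully reproducible, resumable repetition-by-repetition, and
lets any single repetition be regenerated in isolation.

## Fitting six parametric families

The families and parameterizations follow the conventions of the
flexible-survival ecosystem: exponential(rate), Weibull(shape, scale),
log-normal(meanlog, sdlog), log-logistic(shape, scale), generalized
gamma(mu, sigma, Q; Prentice form), Gompertz(shape ∈ ℝ, rate > 0).
Distribution functions for the non-base families come from `flexsurv`.

Maximum likelihood uses the standard right-censoring likelihood (events
contribute log f, censored observations log S), maximized over
unconstrained-scale parameters (positive parameters log-transformed):

* the exponential is fitted in closed form (rate = events / total time at
  risk; Var(log rate) = 1/events);
* other families use BFGS (relative tolerance 1e−10, at most 500
  iterations) from starting values anchored at the exponential fit; the
  generalized gamma — whose likelihood can carry distinct local optima —
  additionally starts from a log-normal anchor (Q = 0) and keeps the better
  optimum; one deterministic Nelder–Mead retry from perturbed starts runs
  if every BFGS attempt fails;
* the Gompertz shape parameter is of order 1/time on day-scale data, so it
  is rescaled (`parscale`) to keep finite-difference gradients conditioned;
* the covariance of the estimates is the inverse observed information at
  the optimum; a singular or non-finite information matrix, optimizer
  failure, an optimum at absurd magnitude (|θ| > 30 on the unconstrained
  scale), or a dataset with zero events all yield `converged = FALSE` with
  a diagnostic reason — never an exception.

The test suite cross-checks these fits family-by-family against
`flexsurvreg` on shared datasets (equal log-likelihoods and comparable
standard errors), and the likelihood closures used in the optimizer's hot
path against the package's reference likelihood.

Information criteria: AIC = −2ℓ + 2k, BIC = −2ℓ + k ln n with n = subjects
(the ecosystem convention; n = events is available), and small-sample
variants AICc = AIC + 2k(k+1)/(n−k−1) and BICc = −2ℓ + k ln(n)·n/(n−k−1).
No standard "BICc" exists; this form applies the same vanishing n/(n−k−1)
inflation to the BIC penalty so that BICc → BIC as n grows, is documented
here as a package choice, and nothing downstream depends on it. Both
corrections are undefined (NA) for n ≤ k + 1, and a fit is simply not a
candidate under a criterion whose value is undefined.

## Implausibility screening and model selection

Before selection, every fit passes through the prespecified screen,
evaluated in fixed order so recorded reasons are comparable across runs:

1. **nonconverged** (no further checks evaluable);
2. **non-descending survival** on 200 geometrically spaced points spanning
   (0, 2·TH] — checked only while S is meaningfully positive (> 1e−8) so
   floating-point underflow of a far tail is not misread as a plateau;
3. **wide CI at the first event time**: the 95% CI of S(t₁) spans more
   than 0.80 probability. "Width > 0.80" is one of two defensible readings
   of a CI "spanning > 80% probability of survival"; it is isolated behind
   this single predicate;
4. **infinite estimates**: median or TH infinite at the MLE, or infinite
   CI bounds; more than 20% of uncertainty draws with infinite TH also
   counts (the CI-failure threshold below);
5. **median beyond the population maximum event time** (measured from
   enrollment, the scale on which medians live).

CIs here and for the estimands use the same machinery: B = 1000 draws from
the multivariate normal on the unconstrained scale at (estimate,
covariance), percentile 2.5/97.5 bounds. This mirrors the default
uncertainty propagation of the flexible-survival ecosystem; a delta-method
alternative exists for cross-checking (the two agree closely for the
exponential at moderate n, as the tests verify). Draws with infinite TH are
excluded from the TH percentiles; beyond 20% exclusions the interval is
declared failed, which feeds reason 4.

Selection takes the minimal criterion value among plausible fits; exact
ties break by parsimony (fewest parameters) then by the fixed family order
exponential → Weibull → log-normal → log-logistic → generalized gamma →
Gompertz. The pseudo-criterion `true_family` forces the exponential
whenever plausible, giving the correctly-specified benchmark. If no
plausible fit remains, an explicit no-selection marker is recorded and the
repetition is excluded from that grouping's measures (`n_reps_used` makes
this visible).

## Estimands and their intervals

From each selected model: median (50% quantile), S(365), TH (99%
quantile), RMST at the population horizon TH_pop, and RMST at the model's
own horizon TH_i. An infinite TH (a plateauing Gompertz with S(∞) =
exp(rate/shape) above 1%) propagates as an explicit `Inf` marker — it is
the screen's job to remove such fits, never the quantile's job to truncate
them.

RMST points use the exponential closed form or adaptive quadrature
(absolute tolerance 1e−6 days); the B-draw interval computations use
64-node Gauss–Legendre quadrature vectorized across draws, which for these
smooth survival functions is accurate far below that tolerance (verified
against the adaptive route in the tests).

One deliberate design choice: **both RMST intervals propagate parameter
uncertainty at a fixed horizon** — TH_pop and the point-estimate TH_i
respectively. Fixing TH_i mirrors how a decision model is actually used:
the lifetime horizon is set from the base-case extrapolation, then
probabilistic analysis runs at that fixed horizon. The horizon's own
sampling error is thus *not* propagated, and this is precisely what makes
sample-horizon RMST intervals under-cover while median, S(365) and
RMST-at-TH_pop intervals attain nominal coverage when the family is
correctly specified — a behaviour the acceptance tests measure. Had each
draw used its own horizon, every exponential estimand would be a monotone
transform of the rate and all coverages would coincide.

The truth to score against defaults to the **population-fitted** values
(exponential MLE on the complete 50,000-individual population, so that the
finite population's sampling error is part of the target); the theoretical
closed forms at λ are available for analytic work, and the two agree to a
fraction of a percent at this population size.

## Performance measures

Per grouping × criterion × estimand: coverage (CIs containing the truth),
MAE, MAPE, RMSE, and the probability of > 20% relative error, with Monte
Carlo standard errors — binomial √(p(1−p)/n) for proportions, sample-SD/√n
for means, delta method for RMSE. Every measure is re-derived in the test
suite by an independent one-pass brute-force implementation and must agree
exactly.

## Problem sizes and what the tests show

The package's acceptance tests run the primary scenario at desk scale:
n_sim = 200 over the full 6 × 10 grid for identification and
implausibility rates (≈ 72,000 fits), n_sim = 500 at corner groupings for
correctly-specified error magnitudes, and n_sim = 300 with intervals for
coverage — sizes chosen so Monte Carlo standard errors are small relative
to the tolerances asserted while the whole suite completes in minutes.
The same runs, at the same sizes, are what `scripts/acceptance.R` performs.

Because the generator *is* the model the truth comes from, passing tests
demonstrate properties of the method under a correctly specified constant
hazard with uniform accrual and purely administrative censoring. They do
not speak to non-constant hazards, loss to follow-up, competing risks,
covariates, or informative censoring — none of which are modelled.

## Known limitations

* Constant hazard only; the package deliberately excludes non-constant
  hazards, cure fractions, splines, competing risks and covariates.
* The implausibility screen's two judgment calls (the wide-CI reading and
  the 20% infinite-draw threshold) are fixed, documented defaults; both
  sit behind single predicates and are easy to vary. The Gompertz, whose
  fitted shape on exponential data is negative about half the time, is the
  family most affected by the infinite-estimate rule.
* The no-standard-form BICc is a package-defined variant.
* Execution is single-process; per-repetition substreams make the results
  independent of execution order, so parallelizing over repetitions would
  not change any output.
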