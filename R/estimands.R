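# Draw B parameter vectors from the multivariate normal approximation to the
# sampling distribution of the estimates on the unconstrained scale, and map
# them back to the natural scale (one row per draw).
draw_parameters <- function(fit, B) {
  stopifnot(inherits(fit, "surv_fit"), fit$converged, B >= 1)
  th <- MASS::mvrnorm(B, mu = fit$est_t, Sigma = fit$cov)
  if (!is.matrix(th)) th <- matrix(th, ncol = length(fit$est_t))
  to_natural_matrix(fit$family, th)
}

#' Point estimates of the HTA estimands from a fitted model
#'
#' The four quantities a health-technology-assessment decision model takes
#' from an extrapolated survival curve: median survival time, one-year
#' survival probability S(365), the lifetime time horizon TH at which the
#' extrapolated curve reaches 1\% survival (the 99th percentile of the
#' distribution), and restricted mean survival time evaluated at two
#' horizons — the fixed population horizon `th_pop` and the model's own
#' estimated horizon TH. An infinite TH (a plateauing curve) propagates as an
#' `Inf` marker into the sample-horizon RMST; resolving it is the
#' plausibility filter's responsibility.
#'
#' @param fit a converged [fit_parametric()] result.
#' @param th_pop population lifetime time horizon in days (finite).
#' @return named list: `median`, `s365`, `th`, `rmst_pop_th`,
#'   `rmst_sample_th` (days / probability).
#' @export
compute_estimands <- function(fit, th_pop) {
  stopifnot(inherits(fit, "surv_fit"), fit$converged, is.finite(th_pop))
  est <- fit$estimates
  med <- surv_quantile(fit$family, est, 0.5)
  th <- surv_quantile(fit$family, est, 0.99)
  list(median = med,
       s365 = surv_prob(fit$family, est, 365),
       th = th,
       rmst_pop_th = rmst(fit$family, est, th_pop),
       rmst_sample_th = if (is.finite(th)) rmst(fit$family, est, th) else Inf)
}

# Per-draw estimand values for B multivariate-normal parameter draws.
# Vectorized: quantile/survival evaluations recycle over the draw matrix and
# RMSTs use batched Gauss-Legendre quadrature. Both RMSTs are evaluated at
# FIXED horizons (the population horizon and the model's point-estimate
# horizon `th_i`): uncertainty in the sample's own time horizon is
# deliberately not propagated into its RMST interval, mirroring the decision
# modelling practice of fixing the lifetime horizon from the base-case
# extrapolation and then propagating parameter uncertainty at that horizon.
# This is what produces the under-coverage of sample-horizon RMST intervals.
estimand_draws <- function(fit, pm, th_pop, th_i, rmst_nodes = 64L) {
  fam <- fit$family
  f <- .families[[fam]]
  med <- suppressWarnings(f$q(0.5, pm))
  med[is.nan(med)] <- Inf
  th <- suppressWarnings(f$q(0.99, pm))
  th[is.nan(th)] <- Inf
  list(median = med,
       s365 = f$p(365, pm, lower.tail = FALSE),
       th = th,
       rmst_pop_th = rmst_batch(fam, pm, th_pop, rmst_nodes),
       rmst_sample_th = if (is.finite(th_i))
         rmst_batch(fam, pm, th_i, rmst_nodes) else rep(Inf, nrow(pm)))
}

#' Estimands with 95\% confidence intervals
#'
#' Point estimates come from the MLE directly; interval bounds are the 2.5th
#' and 97.5th percentiles of the estimands computed over `B` draws from the
#' multivariate normal on the unconstrained parameter scale at the estimated
#' mean and covariance (the standard uncertainty propagation of the
#' flexible-survival ecosystem). Draws whose time horizon is infinite are
#' excluded from the TH percentiles; if more than 20\% of draws are
#' infinite, or the covariance is unusable, the result carries a CI-failure
#' marker (`ci_failure = TRUE`) that feeds the implausibility screen.
#'
#' Both RMST intervals propagate parameter uncertainty at a FIXED horizon —
#' the population horizon `th_pop` and the model's own point-estimate
#' horizon respectively. Fixing the sample horizon mirrors how a decision
#' model sets its lifetime horizon from the base-case extrapolation before
#' probabilistic analysis, and is why sample-horizon RMST intervals
#' under-cover.
#'
#' @inheritParams compute_estimands
#' @param B number of parameter draws (>= 100).
#' @param rmst_nodes Gauss-Legendre order for the batched RMST quadrature.
#' @return a data.frame with one row per estimand (`median`, `s365`, `th`,
#'   `rmst_pop_th`, `rmst_sample_th`) and columns `est`, `lower`, `upper`;
#'   attributes `ci_failure` (logical) and `prop_infinite_th`.
#' @export
interval_estimands <- function(fit, th_pop, B = 1000L, rmst_nodes = 64L) {
  stopifnot(B >= 100)
  pts <- compute_estimands(fit, th_pop)
  pm <- try(draw_parameters(fit, B), silent = TRUE)
  nm <- names(pts)
  if (inherits(pm, "try-error")) {
    out <- data.frame(estimand = nm, est = unlist(pts),
                      lower = NA_real_, upper = NA_real_)
    attr(out, "ci_failure") <- TRUE
    attr(out, "prop_infinite_th") <- NA_real_
    rownames(out) <- NULL
    return(out)
  }
  dr <- estimand_draws(fit, pm, th_pop, th_i = pts$th, rmst_nodes)
  p_inf <- mean(!is.finite(dr$th))
  ci <- function(x, drop_inf = FALSE) {
    if (drop_inf) x <- x[is.finite(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    unname(quantile(x, c(0.025, 0.975), names = FALSE))
  }
  bounds <- rbind(ci(dr$median), ci(dr$s365),
                  ci(dr$th, drop_inf = TRUE),
                  ci(dr$rmst_pop_th),
                  ci(dr$rmst_sample_th, drop_inf = TRUE))
  out <- data.frame(estimand = nm, est = unlist(pts),
                    lower = bounds[, 1], upper = bounds[, 2])
  rownames(out) <- NULL
  attr(out, "ci_failure") <- p_inf > 0.2 || any(!is.finite(bounds))
  attr(out, "prop_infinite_th") <- p_inf
  out
}

#' Population truth for the simulation estimands
#'
#' The true values against which every repetition is scored. Two sources:
#' `"theoretical"` uses the closed forms of the exponential data-generating
#' distribution at the configured hazard (median = -log(0.5)/lambda, TH =
#' -log(0.01)/lambda, RMST at TH = 0.99/lambda); `"population_fit"` (the
#' default used by the pipeline) fits the exponential by maximum likelihood
#' to the complete population's event times and takes the same quantities
#' from the fitted rate, so that sampling error in the finite population is
#' part of the target. The population horizon `th_pop` is this truth's TH.
#'
#' @param config a [scenario_config()] (needed for `"theoretical"`).
#' @param pop a `sim_population` (needed for `"population_fit"`).
#' @param source `"population_fit"` or `"theoretical"`.
#' @return named list: `rate`, `median`, `s365`, `th`, `rmst_pop_th`,
#'   `rmst_sample_th`, `max_event_time`, `source`.
#' @export
population_truth <- function(config = NULL, pop = NULL,
                             source = c("population_fit", "theoretical")) {
  source <- match.arg(source)
  if (source == "theoretical") {
    stopifnot(inherits(config, "scenario_config"))
    rate <- config$lambda12
  } else {
    stopifnot(inherits(pop, "sim_population"))
    tt <- pop$event_times
    rate <- length(tt) / sum(tt) # exponential MLE, complete observation
  }
  th <- -log(0.01) / rate
  list(rate = rate,
       median = -log(0.5) / rate,
       s365 = exp(-365 * rate),
       th = th,
       rmst_pop_th = (1 - 0.01) / rate,
       rmst_sample_th = (1 - 0.01) / rate,
       max_event_time = if (!is.null(pop)) pop$max_event_time else Inf,
       source = source)
}
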