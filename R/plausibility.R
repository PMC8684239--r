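.implausibility_reasons <- c("nonconverged", "non_descending_survival",
                             "wide_ci_first_event", "infinite_estimate",
                             "median_beyond_population_max")

#' Screen a fitted model for implausibility
#'
#' Applies the prespecified conditions under which a fitted survival model is
#' removed before model selection, evaluated in a fixed order so that the
#' recorded reasons are comparable across runs:
#'
#' 1. `nonconverged` — the optimizer failed or the information matrix was
#'    singular (no further checks are evaluable);
#' 2. `non_descending_survival` — S(t) fails to decrease strictly on a grid
#'    of 200 geometrically spaced points on (0, 2 TH\] (checked while S is
#'    still meaningfully positive, so floating-point underflow of a tail near
#'    zero is not flagged);
#' 3. `wide_ci_first_event` — the 95\% CI of S(t) at the first observed event
#'    time spans more than 0.80 probability of survival;
#' 4. `infinite_estimate` — the median or time horizon, or any of their CI
#'    bounds, is infinite (a plateauing extrapolation; more than 20\% of
#'    uncertainty draws with infinite TH also triggers this);
#' 5. `median_beyond_population_max` — the fitted median survival exceeds the
#'    maximum event time in the simulated population.
#'
#' Confidence bounds for checks 3-4 use `B_ci` multivariate-normal parameter
#' draws on the unconstrained scale (see [interval_estimands()]).
#'
#' @param fit a [fit_parametric()] result (converged or not).
#' @param times,events the dataset the model was fitted to.
#' @param pop_max_event_time maximum event time (days from enrollment) in the
#'   simulated population.
#' @param B_ci number of parameter draws for the CI-based checks.
#' @param grid_n number of grid points for the descending-survival check.
#' @return a list of class `plausibility_verdict`: `plausible` (flag),
#'   `reasons` (character subset of the five conditions, empty iff
#'   plausible).
#' @export
assess_plausibility <- function(fit, times, events, pop_max_event_time,
                                B_ci = 1000L, grid_n = 200L) {
  stopifnot(inherits(fit, "surv_fit"), is.finite(pop_max_event_time),
            length(times) > 0)
  reasons <- character(0)
  if (!fit$converged) {
    return(structure(list(plausible = FALSE, reasons = "nonconverged"),
                     class = "plausibility_verdict"))
  }
  fam <- fit$family
  est <- fit$estimates
  med <- surv_quantile(fam, est, 0.5)
  th <- surv_quantile(fam, est, 0.99)

  # 2. strictly descending survival on a geometric grid over (0, 2 TH]
  hc <- if (is.finite(th)) 2 * th else 100 * max(times)
  grid <- exp(seq(log(hc / 1e4), log(hc), length.out = grid_n))
  s <- surv_prob(fam, est, grid)
  live <- s[-length(s)] > 1e-8 # ignore the underflowed far tail
  if (any(diff(s)[live] >= 0)) reasons <- c(reasons, "non_descending_survival")

  # uncertainty draws for the CI-based checks
  pm <- try(draw_parameters(fit, B_ci), silent = TRUE)
  ci_failed <- inherits(pm, "try-error")

  # 3. wide CI of S(t) at the first observed event time
  if (!ci_failed && any(events == 1)) {
    t1 <- min(times[events == 1])
    s1 <- .families[[fam]]$p(t1, pm, lower.tail = FALSE)
    ci1 <- quantile(s1, c(0.025, 0.975), names = FALSE)
    if (ci1[2] - ci1[1] > 0.80) reasons <- c(reasons, "wide_ci_first_event")
  }

  # 4. infinite point estimates or CI bounds
  inf_flag <- !is.finite(med) || !is.finite(th)
  if (!ci_failed) {
    f <- .families[[fam]]
    med_d <- suppressWarnings(f$q(0.5, pm)); med_d[is.nan(med_d)] <- Inf
    th_d <- suppressWarnings(f$q(0.99, pm)); th_d[is.nan(th_d)] <- Inf
    p_inf <- mean(!is.finite(th_d))
    med_ci <- quantile(med_d, c(0.025, 0.975), names = FALSE)
    if (any(!is.finite(med_ci)) || p_inf > 0.2) inf_flag <- TRUE
    if (p_inf <= 0.2 && p_inf > 0) {
      th_ci <- quantile(th_d[is.finite(th_d)], c(0.025, 0.975), names = FALSE)
      if (any(!is.finite(th_ci))) inf_flag <- TRUE
    }
  } else {
    inf_flag <- TRUE # covariance unusable: uncertainty undefined
  }
  if (inf_flag) reasons <- c(reasons, "infinite_estimate")

  # 5. fitted median beyond the population's maximum event time
  if (is.finite(med) && med > pop_max_event_time)
    reasons <- c(reasons, "median_beyond_population_max")

  structure(list(plausible = length(reasons) == 0L, reasons = reasons),
            class = "plausibility_verdict")
}

#' Select the best-fitting family by an information criterion
#'
#' Among the plausible fits, picks the family with the minimal value of the
#' chosen criterion. Exact ties are broken by parsimony (fewest parameters)
#' and then by the fixed family order of [surv_families()]. The pseudo
#' criterion `"true_family"` forces the exponential fit (the data-generating
#' family) whenever it is plausible, for correctly-specified analyses.
#' Fits whose criterion value is undefined (AICc/BICc with n <= k + 1) are
#' not candidates under that criterion.
#'
#' @param fits list of [fit_parametric()] results, one per family.
#' @param verdicts list of matching [assess_plausibility()] verdicts.
#' @param criterion one of `"aic"`, `"bic"`, `"aicc"`, `"bicc"`,
#'   `"true_family"`.
#' @return a list of class `selection_result`: `criterion`, `chosen_family`
#'   (NA with `no_selection = TRUE` if no plausible candidate remains — the
#'   explicit no-selection marker), `chosen_index`, `was_true_family`,
#'   `n_excluded`.
#' @export
select_best <- function(fits, verdicts,
                        criterion = c("aic", "bic", "aicc", "bicc",
                                      "true_family")) {
  criterion <- match.arg(criterion)
  stopifnot(length(fits) == length(verdicts))
  fams <- vapply(fits, function(f) f$family, character(1))
  plausible <- vapply(verdicts, function(v) v$plausible, logical(1))
  n_excluded <- sum(!plausible)
  none <- structure(list(criterion = criterion, chosen_family = NA_character_,
                         chosen_index = NA_integer_, was_true_family = NA,
                         n_excluded = n_excluded, no_selection = TRUE),
                    class = "selection_result")
  if (criterion == "true_family") {
    i <- which(fams == "exponential" & plausible)
    if (length(i) == 0) return(none)
    i <- i[1]
  } else {
    vals <- vapply(fits, function(f) f[[criterion]], numeric(1))
    cand <- which(plausible & is.finite(vals))
    if (length(cand) == 0) return(none)
    best <- cand[vals[cand] == min(vals[cand])]
    if (length(best) > 1) {
      k <- vapply(fits[best], function(f) f$npars, numeric(1))
      best <- best[k == min(k)]
      if (length(best) > 1) {
        ord <- match(fams[best], surv_families())
        best <- best[which.min(ord)]
      }
    }
    i <- best[1]
  }
  structure(list(criterion = criterion, chosen_family = fams[i],
                 chosen_index = i,
                 was_true_family = fams[i] == "exponential",
                 n_excluded = n_excluded, no_selection = FALSE),
            class = "selection_result")
}
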