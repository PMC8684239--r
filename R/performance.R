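#' Coverage of confidence intervals
#'
#' Proportion of repetitions whose 95\% CI contains the true population
#' quantity, with its binomial Monte Carlo standard error
#' sqrt(p(1-p)/n).
#'
#' @param lower,upper CI bounds, one per repetition.
#' @param truth the true population value (finite).
#' @return list `est` (proportion) and `mcse`.
#' @export
coverage <- function(lower, upper, truth) {
  stopifnot(length(lower) == length(upper), length(lower) > 0,
            is.finite(truth))
  hit <- lower <= truth & truth <= upper
  p <- mean(hit)
  list(est = p, mcse = sqrt(p * (1 - p) / length(hit)))
}

#' Error of point estimates against the population truth
#'
#' Mean absolute error, mean absolute percentage error (in percent) and root
#' mean squared error of repetition estimates, each with a Monte Carlo
#' standard error (sample SD of the per-repetition contribution over
#' sqrt(n); for RMSE, the delta-method MCSE of the root of the mean squared
#' error).
#'
#' @param estimates point estimates, one per repetition.
#' @param truth the true population value; must be nonzero (MAPE is relative).
#' @return list with `mae`, `mape`, `rmse` and matching `mcse_*` entries.
#' @export
error_metrics <- function(estimates, truth) {
  stopifnot(length(estimates) > 0, is.finite(truth))
  if (truth == 0) stop("truth must be nonzero for percentage error")
  n <- length(estimates)
  ae <- abs(estimates - truth)
  se <- (estimates - truth)^2
  msq <- mean(se)
  list(mae = mean(ae),
       mcse_mae = sd(ae) / sqrt(n),
       mape = 100 * mean(ae / abs(truth)),
       mcse_mape = 100 * sd(ae / abs(truth)) / sqrt(n),
       rmse = sqrt(msq),
       mcse_rmse = if (msq > 0) sd(se) / sqrt(n) / (2 * sqrt(msq)) else 0)
}

#' Probability of a large relative error
#'
#' Proportion of repetitions whose estimate deviates from the truth by more
#' than a relative threshold (default 20\%) — the chance that a single trial
#' produces a practically meaningful magnitude of error.
#'
#' @inheritParams error_metrics
#' @param threshold relative deviation defining "large" (default 0.2).
#' @return list `est` (proportion) and `mcse`.
#' @export
prob_large_error <- function(estimates, truth, threshold = 0.2) {
  stopifnot(length(estimates) > 0, is.finite(truth))
  if (truth == 0) stop("truth must be nonzero for relative error")
  p <- mean(abs(estimates - truth) / abs(truth) > threshold)
  list(est = p, mcse = sqrt(p * (1 - p) / length(estimates)))
}

#' Proportion of repetitions identifying the true distribution
#'
#' @param was_true logical vector (or list of [select_best()] results), one
#'   entry per repetition, indicating whether the selected family was the
#'   data-generating exponential.
#' @return list `est` (proportion) and `mcse`.
#' @export
prop_true_distribution <- function(was_true) {
  if (is.list(was_true))
    was_true <- vapply(was_true, function(s) isTRUE(s$was_true_family),
                       logical(1))
  stopifnot(length(was_true) > 0)
  p <- mean(was_true)
  list(est = p, mcse = sqrt(p * (1 - p) / length(was_true)))
}

#' Aggregate repetition-level results into a performance table
#'
#' Collapses the long estimand table of a simulation run into one row per
#' (criterion, estimand, n_obs, p_e) grouping, carrying all performance
#' measures with Monte Carlo standard errors. Repetitions with a no-selection
#' or CI-failure marker (non-finite point estimate, or missing CI bounds when
#' coverage is requested) are excluded from that grouping's measures;
#' `n_reps_used` makes the exclusions visible.
#'
#' @param estimands a data.frame with columns `rep`, `n_obs`, `pe`,
#'   `criterion`, `estimand`, `est` and (optionally) `lower`, `upper`, as
#'   produced by [run_scenario()].
#' @param truth a [population_truth()] list.
#' @param threshold relative threshold for the probability-of-large-error
#'   measure.
#' @return a data.frame, one row per grouping x estimand x criterion, with
#'   columns `n_reps_used`, `coverage`, `mcse_coverage` (NA without CIs),
#'   `mae`, `mape`, `rmse`, `prob_20pct_error` and their MCSEs.
#' @export
performance_table <- function(estimands, truth, threshold = 0.2) {
  need <- c("rep", "n_obs", "pe", "criterion", "estimand", "est")
  stopifnot(all(need %in% names(estimands)))
  has_ci <- all(c("lower", "upper") %in% names(estimands))
  groups <- unique(estimands[c("criterion", "estimand", "n_obs", "pe")])
  groups <- groups[order(groups$criterion, groups$estimand, groups$n_obs,
                         groups$pe), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- estimands$criterion == g$criterion &
      estimands$estimand == g$estimand &
      estimands$n_obs == g$n_obs & abs(estimands$pe - g$pe) < 1e-9
    x <- estimands[sel, ]
    tv <- truth[[g$estimand]]
    ok <- is.finite(x$est)
    x <- x[ok, ]
    n_used <- nrow(x)
    if (n_used == 0 || !is.finite(tv)) {
      em <- list(mae = NA_real_, mcse_mae = NA_real_, mape = NA_real_,
                 mcse_mape = NA_real_, rmse = NA_real_, mcse_rmse = NA_real_)
      pl <- list(est = NA_real_, mcse = NA_real_)
    } else {
      em <- error_metrics(x$est, tv)
      pl <- prob_large_error(x$est, tv, threshold)
    }
    if (has_ci && is.finite(tv)) {
      xc <- estimands[sel, ]
      xc <- xc[is.finite(xc$est) & is.finite(xc$lower) & is.finite(xc$upper), ]
      cv <- if (nrow(xc) > 0) coverage(xc$lower, xc$upper, tv)
            else list(est = NA_real_, mcse = NA_real_)
      n_cov <- nrow(xc)
    } else {
      cv <- list(est = NA_real_, mcse = NA_real_)
      n_cov <- NA_integer_
    }
    data.frame(criterion = g$criterion, estimand = g$estimand,
               n_obs = g$n_obs, pe = g$pe, n_reps_used = n_used,
               n_reps_ci = n_cov,
               coverage = cv$est, mcse_coverage = cv$mcse,
               mae = em$mae, mcse_mae = em$mcse_mae,
               mape = em$mape, mcse_mape = em$mcse_mape,
               rmse = em$rmse, mcse_rmse = em$mcse_rmse,
               prob_20pct_error = pl$est, mcse_prob_20pct_error = pl$mcse)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
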