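# Shared fixtures: all synthetic, generated in code at test time.

# A small right-censored exponential dataset with a fixed seed.
make_censored_data <- function(n = 50, rate = 0.0025, cens = 400, seed = 1) {
  set.seed(seed)
  ev <- rexp(n, rate)
  time <- pmin(ev, cens)
  data.frame(time = time, event = as.integer(ev <= cens))
}

# Hand-build a converged surv_fit object at known parameter values with a
# near-degenerate covariance, for testing downstream consumers in isolation
# from the optimizer.
fake_fit <- function(family, estimates, var = 1e-10, n = 100, d = 80) {
  est_t <- extrapsim:::to_unconstrained(family, estimates)
  k <- length(estimates)
  ll <- -100
  ic <- information_criteria(ll, k, n)
  structure(list(family = family,
                 estimates = setNames(estimates, family_spec(family)$pars),
                 est_t = est_t, cov = diag(var, k), loglik = ll,
                 npars = k, n = n, n_events = d, converged = TRUE,
                 reason = NA_character_,
                 aic = unname(ic["aic"]), bic = unname(ic["bic"]),
                 aicc = unname(ic["aicc"]), bicc = unname(ic["bicc"])),
            class = "surv_fit")
}

# A tiny scenario for pipeline tests: full machinery, desk-scale grid.
tiny_config <- function(n_sim = 2, seed = 7) {
  scenario_config(lambda12 = 0.0025, T1 = 270, pop_size = 2000,
                  n_sim = n_sim, n_obs_levels = c(30, 60),
                  pe_levels = c(0.5, 1), seed = seed)
}
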