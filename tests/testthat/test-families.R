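test_that("exponential closed forms: survival, quantiles, RMST", {
  r <- 0.0025
  expect_equal(surv_prob("exponential", r, 0), 1)
  expect_equal(surv_prob("exponential", r, -log(0.5) / r), 0.5)
  expect_equal(surv_prob("exponential", r, 365), 0.401519, tolerance = 1e-6)
  expect_equal(surv_quantile("exponential", r, 0.5), 277.2589,
               tolerance = 1e-4)
  expect_equal(surv_quantile("exponential", r, 0.99), 1842.068,
               tolerance = 1e-4)
  # RMST to the 1% survival time is (1 - 0.01)/rate
  expect_equal(rmst("exponential", r, 1842.068), 396.0, tolerance = 1e-3)
  expect_equal(rmst("exponential", r, 0), 0)
})

test_that("survival functions are monotone, bounded and start at 1", {
  params <- list(exponential = 0.003, weibull = c(1.4, 350),
                 lognormal = c(5.5, 1.1), loglogistic = c(1.8, 300),
                 gengamma = c(5.8, 0.9, 0.5), gompertz = c(0.002, 0.001))
  tt <- c(0, 1, 10, 100, 500, 2000, 10000)
  for (fam in surv_families()) {
    s <- surv_prob(fam, params[[fam]], tt)
    expect_equal(s[1], 1, info = fam)
    expect_true(all(diff(s) <= 0), info = fam)
    expect_true(all(s >= 0 & s <= 1), info = fam)
  }
})

test_that("quantile and survival compose to identity for all families", {
  params <- list(exponential = 0.003, weibull = c(1.4, 350),
                 lognormal = c(5.5, 1.1), loglogistic = c(1.8, 300),
                 gengamma = c(5.8, 0.9, 0.5), gompertz = c(0.002, 0.001))
  p <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  for (fam in surv_families()) {
    q <- surv_quantile(fam, params[[fam]], p)
    expect_equal(surv_prob(fam, params[[fam]], q), 1 - p,
                 tolerance = 1e-8, info = fam)
  }
})

test_that("plateauing Gompertz returns the infinite-quantile marker", {
  # S(Inf) = exp(rate/shape) = exp(-0.1) = 0.905 > 0.01: the 1% survival
  # time is never reached
  expect_identical(surv_quantile("gompertz", c(-0.01, 0.001), 0.99), Inf)
  # but quantiles above the plateau are still finite
  expect_true(is.finite(surv_quantile("gompertz", c(-0.01, 0.001), 0.05)))
})

test_that("family reductions agree in survival and log-likelihood", {
  d <- make_censored_data(n = 60, seed = 3)
  tt <- c(10, 100, 400, 1000)
  # Weibull with shape 1 is exponential
  expect_equal(surv_prob("weibull", c(1, 400), tt),
               surv_prob("exponential", 1 / 400, tt), tolerance = 1e-12)
  expect_equal(surv_loglik("weibull", c(1, 400), d$time, d$event),
               surv_loglik("exponential", 1 / 400, d$time, d$event),
               tolerance = 1e-6)
  # generalized gamma: Q = 1 is Weibull(shape = 1/sigma, scale = exp(mu));
  # Q = 0 is log-normal(mu, sigma)
  expect_equal(surv_loglik("gengamma", c(log(350), 1 / 1.4, 1),
                           d$time, d$event),
               surv_loglik("weibull", c(1.4, 350), d$time, d$event),
               tolerance = 1e-6)
  expect_equal(surv_loglik("gengamma", c(5.5, 1.1, 0), d$time, d$event),
               surv_loglik("lognormal", c(5.5, 1.1), d$time, d$event),
               tolerance = 1e-6)
  # Gompertz with shape 0 is exponential
  expect_equal(surv_loglik("gompertz", c(0, 0.0025), d$time, d$event),
               surv_loglik("exponential", 0.0025, d$time, d$event),
               tolerance = 1e-6)
})

test_that("right-censored log-likelihood matches hand computation", {
  # three events at rate 0.005: 3 log(0.005) - 0.005 * 600
  expect_equal(surv_loglik("exponential", 0.005, c(100, 200, 300),
                           c(1, 1, 1)),
               3 * log(0.005) - 3, tolerance = 1e-12)
  # all censored: no density terms, only -rate * total time
  expect_equal(surv_loglik("exponential", 0.005, c(100, 200, 300),
                           c(0, 0, 0)),
               -0.005 * 600, tolerance = 1e-12)
})

test_that("optimizer-path likelihoods equal the reference likelihood", {
  # the fast closures used inside fit_parametric against the registry route
  set.seed(11)
  d <- make_censored_data(n = 40, seed = 11)
  thetas <- list(weibull = c(0.3, log(300)), lognormal = c(5.6, 0.1),
                 loglogistic = c(0.4, log(280)),
                 gengamma = c(5.7, -0.2, 0.7), gompertz = c(0.001, log(0.002)))
  for (fam in names(thetas)) {
    nll <- extrapsim:::make_nll(fam, d$time, d$event)
    pars <- extrapsim:::to_natural(fam, thetas[[fam]])
    expect_equal(-nll(thetas[[fam]]),
                 surv_loglik(fam, pars, d$time, d$event),
                 tolerance = 1e-8, info = fam)
  }
})

test_that("RMST quadrature matches closed forms and respects bounds", {
  # Weibull(1, 400) is exponential(1/400): quadrature vs closed form
  for (h in c(100, 1000, 5000)) {
    expect_equal(rmst("weibull", c(1, 400), h),
                 (1 - exp(-h / 400)) * 400, tolerance = 1e-6)
  }
  for (fam in surv_families()) {
    p <- list(exponential = 0.003, weibull = c(1.4, 350),
              lognormal = c(5.5, 1.1), loglogistic = c(1.8, 300),
              gengamma = c(5.8, 0.9, 0.5), gompertz = c(0.002, 0.001))[[fam]]
    v <- rmst(fam, p, 1500)
    expect_true(v >= 0 && v <= 1500, info = fam)
  }
  expect_error(rmst("exponential", 0.0025, Inf), "finite")
})

test_that("batched Gauss-Legendre RMST agrees with adaptive quadrature", {
  pm <- rbind(c(5.8, 0.9, 0.5), c(6.2, 1.1, -0.3), c(5.5, 0.7, 1.2))
  got <- extrapsim:::rmst_batch("gengamma", pm, c(800, 1500, 3000))
  want <- sapply(1:3, function(i)
    rmst("gengamma", pm[i, ], c(800, 1500, 3000)[i]))
  expect_equal(got, want, tolerance = 1e-6)
  # non-finite horizon propagates the Inf marker
  expect_identical(extrapsim:::rmst_batch("exponential",
                                          matrix(0.0025, 1, 1), Inf), Inf)
})

test_that("information-criterion ranking is invariant to time rescaling", {
  d <- make_censored_data(n = 120, seed = 5)
  fams <- surv_families()
  aic_days <- sapply(fams, function(f)
    fit_parametric(d$time, d$event, f)$aic)
  aic_months <- sapply(fams, function(f)
    fit_parametric(d$time / 30, d$event, f)$aic)
  # the Jacobian of the time rescaling shifts every family's loglik by the
  # same n_events * log(30), so pairwise AIC differences are unchanged
  expect_equal(aic_days - aic_days["exponential"],
               aic_months - aic_months["exponential"], tolerance = 1e-3)
  expect_equal(order(aic_days), order(aic_months))
})
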