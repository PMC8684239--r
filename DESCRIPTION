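Package: extrapsim
Title: Simulation of Parametric Survival Extrapolation Under Limited Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation machinery for quantifying the coverage and
    error of parametric survival extrapolation when clinical time-to-event data
    are limited by small sample size or short follow-up. Simulates trial
    populations with staggered accrual and exponential event times, draws study
    samples, and censors them administratively at successive event-proportion
    deciles. Fits six standard parametric families (exponential, Weibull,
    log-normal, log-logistic, generalized gamma, Gompertz) by right-censored
    maximum likelihood, screens fits for nonconvergence and implausibility,
    selects best-fitting families by information criteria (AIC, BIC, AICc,
    BICc), and evaluates estimands relevant to health technology assessment
    (median survival, one-year survival, lifetime time horizon, restricted mean
    survival time) against population truth, with Monte Carlo standard errors
    for all performance measures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    flexsurv,
    MASS,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
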