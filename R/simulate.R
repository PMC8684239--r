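#' Scenario configuration for the trial simulation
#'
#' Bundles the data-generating parameters of one simulation scenario: the
#' constant event hazard, the accrual window, the population size, and the
#' grid of sample sizes and event-proportion levels at which samples are
#' analyzed.
#'
#' @param lambda12 event hazard per day (> 0).
#' @param T1 maximum accrual time in days (>= 1); enrollment times are
#'   uniform on \[1, T1\].
#' @param pop_size number of individuals in the simulated population.
#' @param n_sim number of simulation repetitions.
#' @param n_obs_levels strictly increasing sample sizes drawn per repetition.
#' @param pe_levels strictly increasing event proportions in (0, 1\] at which
#'   each sample is administratively censored; the last level must be 1
#'   (complete follow-up).
#' @param seed master RNG seed; every random draw in a run derives from it.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(lambda12 = 0.0025, T1 = 270, pop_size = 50000,
                            n_sim = 5000,
                            n_obs_levels = c(30, 60, 90, 120, 250, 500),
                            pe_levels = seq(0.1, 1, by = 0.1),
                            seed = 1L) {
  if (!is.numeric(lambda12) || lambda12 <= 0)
    stop("lambda12 must be a positive hazard per day")
  if (!is.numeric(T1) || T1 < 1) stop("T1 must be at least 1 day")
  if (pop_size < max(n_obs_levels))
    stop("pop_size must be at least the largest sample size")
  if (is.unsorted(n_obs_levels, strictly = TRUE))
    stop("n_obs_levels must be strictly increasing")
  if (is.unsorted(pe_levels, strictly = TRUE) ||
      any(pe_levels <= 0) || abs(pe_levels[length(pe_levels)] - 1) > 1e-12)
    stop("pe_levels must be strictly increasing in (0, 1] with last level 1")
  structure(list(lambda12 = lambda12, T1 = T1,
                 pop_size = as.integer(pop_size), n_sim = as.integer(n_sim),
                 n_obs_levels = as.integer(n_obs_levels),
                 pe_levels = pe_levels, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Bundled scenario presets
#'
#' Four scenarios crossing accrual length with event rate: short accrual
#' (9 months = 270 days at 30 days/month) or long accrual (30 months = 900
#' days), and high hazard (0.0025/day, median about 277 days) or low hazard
#' (0.00075/day, median about 924 days).
#'
#' @param scenario scenario number 1-4.
#' @param ... overrides passed on to [scenario_config()] (e.g. `n_sim`,
#'   `seed`).
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(scenario = 1, ...) {
  stopifnot(scenario %in% 1:4)
  grid <- list(list(T1 = 270, lambda12 = 0.0025),
               list(T1 = 900, lambda12 = 0.0025),
               list(T1 = 270, lambda12 = 0.00075),
               list(T1 = 900, lambda12 = 0.00075))
  p <- grid[[scenario]]
  scenario_config(lambda12 = p$lambda12, T1 = p$T1, ...)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Trial simulation scenario\n")
  cat("  hazard lambda12 =", x$lambda12, "per day (median",
      round(-log(0.5) / x$lambda12, 1), "days)\n")
  cat("  accrual uniform on [1,", x$T1, "] days;  population",
      x$pop_size, "\n")
  cat("  n_sim =", x$n_sim, "; n_obs = {",
      paste(x$n_obs_levels, collapse = ", "), "}; p_e = {",
      paste(x$pe_levels, collapse = ", "), "}\n")
  cat("  master seed", x$seed, "\n")
  invisible(x)
}

#' Generate a ground-truth population
#'
#' Simulates the complete cohort from which study samples are drawn:
#' enrollment times uniform on \[1, T1\] (staggered accrual) and event times
#' from enrollment exponential with rate `lambda12`, for `pop_size`
#' individuals. All event times are known — censoring is introduced only
#' later, per sample, by administrative truncation.
#'
#' @param config a [scenario_config()].
#' @return an object of class `sim_population`: list with `enroll_times`
#'   (days from study start), `event_times` (days from enrollment),
#'   `true_rate`, `max_event_time` (max days from enrollment) and
#'   `max_event_calendar_time` (max enrollment + event time).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  enroll <- runif(config$pop_size, min = 1, max = config$T1)
  event <- rexp(config$pop_size, rate = config$lambda12)
  structure(list(enroll_times = enroll, event_times = event,
                 true_rate = config$lambda12,
                 max_event_time = max(event),
                 max_event_calendar_time = max(enroll + event)),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated population of", length(x$event_times), "individuals\n")
  cat("  true hazard", x$true_rate, "per day; empirical median event time",
      round(stats::median(x$event_times), 1), "days\n")
  cat("  max event time", round(x$max_event_time, 1),
      "days from enrollment (", round(x$max_event_calendar_time, 1),
      "calendar )\n")
  invisible(x)
}

#' Draw a study sample from the population
#'
#' @param pop a `sim_population`.
#' @param n_obs sample size; must not exceed the population size.
#' @return integer indices of `n_obs` distinct individuals, drawn uniformly
#'   without replacement.
#' @export
draw_sample <- function(pop, n_obs) {
  stopifnot(inherits(pop, "sim_population"))
  k <- length(pop$event_times)
  if (n_obs > k) stop("n_obs exceeds the population size")
  sample.int(k, n_obs, replace = FALSE)
}

#' Calendar censoring time for a target proportion of events
#'
#' Finds the follow-up time, measured from the start of the study, by which a
#' proportion `p_e` of the sample has experienced the event: the
#' ceiling(p_e * n)-th smallest calendar event time (enrollment + event
#' time). Ties in calendar event times are broken by stable sort order.
#'
#' @param enrolls enrollment times (days from study start) of the sample.
#' @param events event times (days from enrollment) of the sample.
#' @param p_e target proportion of events in (0, 1\].
#' @return the calendar censoring time in days from study start.
#' @export
censor_time_for_proportion <- function(enrolls, events, p_e) {
  n <- length(enrolls)
  if (n == 0L) stop("empty sample")
  stopifnot(length(events) == n, p_e > 0, p_e <= 1)
  rank_needed <- ceiling(p_e * n)
  sort(enrolls + events)[rank_needed]
}

#' Administratively censor a sample at a calendar time
#'
#' Truncates a complete sample's follow-up at calendar time `c`, mimicking a
#' trial stopped on a specific calendar day: individuals enrolled at or after
#' `c` are excluded (not yet accrued), individuals whose event falls at or
#' before `c` keep their observed event, and the remainder are censored at
#' `c` minus their enrollment time. The clock is reset at enrollment: all
#' returned times are days from enrollment.
#'
#' @inheritParams censor_time_for_proportion
#' @param c calendar censoring time (days from study start); must exceed the
#'   earliest enrollment in the sample.
#' @return a data.frame with columns `time` (days from enrollment) and
#'   `event` (1 = event observed, 0 = censored).
#' @export
apply_administrative_censoring <- function(enrolls, events, c) {
  stopifnot(length(enrolls) == length(events))
  if (c <= min(enrolls))
    stop("censoring time precedes every enrollment; the dataset would be empty")
  accrued <- enrolls < c
  en <- enrolls[accrued]
  ev <- events[accrued]
  observed <- en + ev <= c
  data.frame(time = ifelse(observed, ev, c - en),
             event = as.integer(observed))
}

#' Build the full grid of artificially censored datasets
#'
#' For each repetition, one sample per sample-size level is drawn from the
#' population; every event-proportion level then censors that SAME sample at
#' the calendar time by which the target proportion of its events has
#' occurred. Follow-up is therefore nested: higher `p_e` never shortens any
#' individual's observation.
#'
#' Each repetition consumes its own RNG substream derived from the master
#' seed (see [substream_seed()]), so the grid is fully reproducible and any
#' repetition can be regenerated in isolation.
#'
#' @param pop a `sim_population`.
#' @param config the [scenario_config()] used to generate it.
#' @param reps repetitions to generate (default all `1:n_sim`).
#' @return a data.frame in long format with columns `id` (index into the
#'   population), `time`, `event`, `rep`, `n_obs`, `pe`; one row per
#'   individual per dataset.
#' @export
build_dataset_grid <- function(pop, config, reps = seq_len(config$n_sim)) {
  stopifnot(inherits(pop, "sim_population"),
            inherits(config, "scenario_config"))
  reps <- as.integer(reps)
  out <- vector("list", length(reps) * length(config$n_obs_levels) *
                  length(config$pe_levels))
  i <- 0L
  for (r in reps) {
    set.seed(substream_seed(config$seed, r))
    for (n_obs in config$n_obs_levels) {
      idx <- draw_sample(pop, n_obs)
      en <- pop$enroll_times[idx]
      ev <- pop$event_times[idx]
      for (pe in config$pe_levels) {
        ctime <- censor_time_for_proportion(en, ev, pe)
        keep <- en < ctime
        ds <- apply_administrative_censoring(en, ev, ctime)
        i <- i + 1L
        out[[i]] <- data.frame(id = idx[keep], time = ds$time,
                               event = ds$event, rep = r, n_obs = n_obs,
                               pe = pe)
      }
    }
  }
  do.call(rbind, out)
}

#' Write a dataset grid as delimited text
#'
#' @param grid a data.frame from [build_dataset_grid()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_dataset_grid <- function(grid, path, sep = "\t") {
  utils::write.table(grid, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
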