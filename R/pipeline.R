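#' Run a full simulation scenario
#'
#' End-to-end Monte Carlo pipeline: generate the population, then for every
#' repetition, sample size and event-proportion level — draw the sample,
#' censor it administratively, fit the requested parametric families, screen
#' each fit for nonconvergence and implausibility, select the best-fitting
#' family under each information criterion (the correctly-specified
#' `"true_family"` analysis is always included), and collect the HTA
#' estimands of each selected model. Everything derives deterministically
#' from the master seed via per-repetition substreams, so a run is
#' reproducible and resumable repetition by repetition.
#'
#' @param config a [scenario_config()].
#' @param criteria information criteria to select by (subset of
#'   `"aic"`, `"bic"`, `"aicc"`, `"bicc"`); `"true_family"` is always added.
#' @param families families to fit (default all six); restrict to
#'   `"exponential"` for correctly-specified-only analyses.
#' @param truth_source `"population_fit"` (default: estimands scored against
#'   the exponential fitted to the complete population) or `"theoretical"`.
#' @param B_ci multivariate-normal draws for CI-based plausibility checks and
#'   (when `compute_ci`) interval estimands.
#' @param compute_ci also compute 95\% CIs for the selected models'
#'   estimands (needed for coverage; costs roughly 2x).
#' @param out_dir optional directory; per-repetition results are appended to
#'   tab-delimited files there as they complete, enabling `resume`.
#' @param resume if TRUE and `out_dir` holds a partial run, only missing
#'   repetitions are computed; the final tables are identical to a fresh run.
#' @param progress print a line every `progress` repetitions (0 = silent).
#' @return an object of class `scenario_run`: list with `config`, `truth`,
#'   `fits`, `selections`, `estimands` (data.frames) and `manifest`.
#' @export
run_scenario <- function(config, criteria = c("aic", "bic"),
                         families = surv_families(),
                         truth_source = c("population_fit", "theoretical"),
                         B_ci = 1000L, compute_ci = FALSE, out_dir = NULL,
                         resume = FALSE, progress = 0L) {
  stopifnot(inherits(config, "scenario_config"))
  truth_source <- match.arg(truth_source)
  families <- match.arg(families, surv_families(), several.ok = TRUE)
  criteria <- unique(c(setdiff(criteria, "true_family"), "true_family"))
  bad <- setdiff(criteria, c("aic", "bic", "aicc", "bicc", "true_family"))
  if (length(bad)) stop("unknown criteria: ", paste(bad, collapse = ", "))
  t_start <- Sys.time()

  use_files <- !is.null(out_dir)
  if (use_files) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
    paths <- file.path(out_dir, c(fits = "fits.tsv",
                                  selections = "selections.tsv",
                                  estimands = "estimands.tsv",
                                  done = "reps_done.txt"))
    names(paths) <- c("fits", "selections", "estimands", "done")
    if (!resume) unlink(paths)
  }

  pop <- generate_population(config)
  truth <- population_truth(config, pop, source = truth_source)
  th_pop <- truth$th
  pop_max <- pop$max_event_time

  done <- integer(0)
  if (use_files && resume && file.exists(paths["done"]))
    done <- as.integer(readLines(paths["done"]))
  todo <- setdiff(seq_len(config$n_sim), done)

  acc_fits <- list(); acc_sel <- list(); acc_est <- list()
  for (r in todo) {
    rr <- simulate_repetition(r, pop, config, criteria, families, th_pop,
                              pop_max, B_ci, compute_ci)
    if (use_files) {
      append_tsv(rr$fits, paths["fits"])
      append_tsv(rr$selections, paths["selections"])
      append_tsv(rr$estimands, paths["estimands"])
      cat(r, "\n", file = paths["done"], append = TRUE)
    } else {
      acc_fits[[length(acc_fits) + 1L]] <- rr$fits
      acc_sel[[length(acc_sel) + 1L]] <- rr$selections
      acc_est[[length(acc_est) + 1L]] <- rr$estimands
    }
    if (progress > 0 && (r %% progress == 0))
      message("repetition ", r, " / ", config$n_sim, " done")
  }

  if (use_files) {
    fits <- read_tsv_sorted(paths["fits"])
    selections <- read_tsv_sorted(paths["selections"])
    estimands <- read_tsv_sorted(paths["estimands"])
  } else {
    fits <- do.call(rbind, acc_fits)
    selections <- do.call(rbind, acc_sel)
    estimands <- do.call(rbind, acc_est)
  }

  n_datasets <- config$n_sim * length(config$n_obs_levels) *
    length(config$pe_levels)
  reason_counts <- reason_tally(fits$reasons)
  manifest <- list(
    config = config, master_seed = config$seed, criteria = criteria,
    families = families, truth_source = truth_source, B_ci = B_ci,
    n_datasets = n_datasets,
    n_fits = n_datasets * length(families),
    n_nonconverged = sum(!fits$converged),
    n_implausible = sum(fits$converged & !fits$plausible),
    implausibility_reasons = reason_counts,
    n_no_selection = sum(selections$no_selection),
    out_dir = if (use_files) normalizePath(out_dir) else NA_character_,
    wall_time_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  structure(list(config = config, truth = truth, fits = fits,
                 selections = selections, estimands = estimands,
                 manifest = manifest),
            class = "scenario_run")
}

# One repetition of the simulation: all sample sizes and censoring levels.
# Consumes the repetition's own RNG substream.
simulate_repetition <- function(r, pop, config, criteria, families, th_pop,
                                pop_max, B_ci, compute_ci) {
  set.seed(substream_seed(config$seed, r))
  f_rows <- list(); s_rows <- list(); e_rows <- list()
  for (n_obs in config$n_obs_levels) {
    idx <- draw_sample(pop, n_obs)
    en <- pop$enroll_times[idx]
    ev <- pop$event_times[idx]
    for (pe in config$pe_levels) {
      ctime <- censor_time_for_proportion(en, ev, pe)
      ds <- apply_administrative_censoring(en, ev, ctime)
      fits <- lapply(families, function(fam)
        fit_parametric(ds$time, ds$event, fam))
      verdicts <- lapply(fits, function(f)
        assess_plausibility(f, ds$time, ds$event, pop_max, B_ci = B_ci))
      f_rows[[length(f_rows) + 1L]] <- data.frame(
        rep = r, n_obs = n_obs, pe = pe,
        family = vapply(fits, `[[`, character(1), "family"),
        converged = vapply(fits, `[[`, logical(1), "converged"),
        plausible = vapply(verdicts, `[[`, logical(1), "plausible"),
        reasons = vapply(verdicts, function(v)
          paste(v$reasons, collapse = ";"), character(1)),
        loglik = vapply(fits, `[[`, numeric(1), "loglik"),
        aic = vapply(fits, `[[`, numeric(1), "aic"),
        bic = vapply(fits, `[[`, numeric(1), "bic"),
        aicc = vapply(fits, `[[`, numeric(1), "aicc"),
        bicc = vapply(fits, `[[`, numeric(1), "bicc"))
      for (crit in criteria) {
        sel <- select_best(fits, verdicts, crit)
        s_rows[[length(s_rows) + 1L]] <- data.frame(
          rep = r, n_obs = n_obs, pe = pe, criterion = crit,
          chosen_family = sel$chosen_family,
          was_true_family = sel$was_true_family,
          n_excluded = sel$n_excluded, no_selection = sel$no_selection)
        if (!sel$no_selection) {
          fit <- fits[[sel$chosen_index]]
          if (compute_ci) {
            ie <- interval_estimands(fit, th_pop, B = B_ci)
            e_rows[[length(e_rows) + 1L]] <- data.frame(
              rep = r, n_obs = n_obs, pe = pe, criterion = crit,
              estimand = ie$estimand, est = ie$est, lower = ie$lower,
              upper = ie$upper,
              ci_failure = attr(ie, "ci_failure"))
          } else {
            pts <- compute_estimands(fit, th_pop)
            e_rows[[length(e_rows) + 1L]] <- data.frame(
              rep = r, n_obs = n_obs, pe = pe, criterion = crit,
              estimand = names(pts), est = unlist(pts))
          }
        }
      }
    }
  }
  list(fits = do.call(rbind, f_rows),
       selections = do.call(rbind, s_rows),
       estimands = do.call(rbind, e_rows))
}

append_tsv <- function(df, path) {
  if (is.null(df)) return(invisible())
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = !file.exists(path), quote = FALSE,
                     append = file.exists(path))
}

read_tsv_sorted <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  keys <- intersect(c("rep", "n_obs", "pe", "criterion", "estimand",
                      "family"), names(df))
  df <- df[do.call(order, df[keys]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

reason_tally <- function(reasons) {
  parts <- unlist(strsplit(reasons[nzchar(reasons)], ";", fixed = TRUE))
  out <- setNames(integer(length(.implausibility_reasons)),
                  .implausibility_reasons)
  tb <- table(parts)
  out[names(tb)] <- as.integer(tb)
  out
}

#' @export
print.scenario_run <- function(x, ...) {
  m <- x$manifest
  cat("Scenario run:", m$n_datasets, "datasets,", m$n_fits,
      "fits attempted\n")
  cat("  nonconverged:", m$n_nonconverged, "; implausible:",
      m$n_implausible, sprintf("(%.1f%% of fits)\n",
      100 * (m$n_nonconverged + m$n_implausible) / m$n_fits))
  cat("  criteria:", paste(m$criteria, collapse = ", "),
      "; truth:", m$truth_source, "\n")
  cat("  wall time:", round(m$wall_time_sec, 1), "s\n")
  invisible(x)
}

#' Slice the performance table of a run
#'
#' Aggregates a run's estimand table with [performance_table()] and filters
#' it by criterion, estimand, sample size or event proportion. An unknown
#' estimand name yields an empty slice with a warning. Multiple runs
#' (scenarios) can be summarized separately and concatenated by the caller.
#'
#' @param run a `scenario_run`.
#' @param criterion,estimand,n_obs,pe optional filters; NULL keeps all.
#' @param threshold relative threshold for the probability-of-large-error
#'   column.
#' @return the filtered performance data.frame.
#' @export
summarize_performance <- function(run, criterion = NULL, estimand = NULL,
                                  n_obs = NULL, pe = NULL, threshold = 0.2) {
  stopifnot(inherits(run, "scenario_run"))
  tbl <- performance_table(run$estimands, run$truth, threshold = threshold)
  if (!is.null(estimand) && !any(estimand %in% tbl$estimand))
    warning("estimand(s) not present in this run: ",
            paste(setdiff(estimand, tbl$estimand), collapse = ", "))
  keep <- rep(TRUE, nrow(tbl))
  if (!is.null(criterion)) keep <- keep & tbl$criterion %in% criterion
  if (!is.null(estimand)) keep <- keep & tbl$estimand %in% estimand
  if (!is.null(n_obs)) keep <- keep & tbl$n_obs %in% n_obs
  if (!is.null(pe)) keep <- keep & sapply(tbl$pe, function(p)
    any(abs(p - pe) < 1e-9))
  out <- tbl[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a performance table as delimited text
#'
#' @param tbl a data.frame from [performance_table()] or
#'   [summarize_performance()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_performance_table <- function(tbl, path, sep = "\t") {
  utils::write.table(tbl, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' The file carries exactly the [scenario_config()] fields plus the pipeline
#' settings `B_ci` (CI draws) and `truth_source`. Four bundled presets live
#' under `system.file("extdata", package = "extrapsim")`.
#'
#' @param path path to a YAML configuration file.
#' @return a list with `config` (a `scenario_config`), `B_ci`,
#'   `truth_source`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg_fields <- c("lambda12", "T1", "pop_size", "n_sim", "n_obs_levels",
                  "pe_levels", "seed")
  unknown <- setdiff(names(y), c(cfg_fields, "B_ci", "truth_source"))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  config <- do.call(scenario_config, y[intersect(names(y), cfg_fields)])
  list(config = config,
       B_ci = as.integer(y$B_ci %||% 1000L),
       truth_source = y$truth_source %||% "population_fit")
}

#' Write a scenario configuration to a YAML file
#'
#' @param config a [scenario_config()].
#' @param path output path.
#' @param B_ci,truth_source pipeline settings stored alongside the scenario.
#' @export
write_scenario_config <- function(config, path, B_ci = 1000L,
                                  truth_source = "population_fit") {
  stopifnot(inherits(config, "scenario_config"))
  y <- unclass(config)
  y$B_ci <- B_ci
  y$truth_source <- truth_source
  yaml::write_yaml(y, path)
  invisible(path)
}
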