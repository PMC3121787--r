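# Sampling-design evaluation: Monte-Carlo bias/precision of turnover
# parameter estimates under candidate sampling schedules and sample sizes.

.validate_schedule <- function(days, label = "schedule") {
  if (!is.numeric(days) || length(days) < 4) {
    abort(sprintf("%s must contain >= 4 sampling days.", label))
  }
  if (days[1] != 0 || is.unsorted(days, strictly = TRUE)) {
    abort(sprintf("%s must be strictly increasing and include day 0.",
                  label))
  }
  invisible(days)
}

#' Scenario for a sampling-design simulation
#'
#' @param truth A [trajectory_truth()]; its schedule is ignored in favour of
#'   the candidate schedules.
#' @param schedules Named list of candidate day vectors; each needs at least
#'   4 points including day 0 (validated before any simulation runs).
#' @param n_replicates Monte-Carlo replicates per schedule (default 200).
#' @param spec A [population_spec()] giving the simulated individuals.
#' @param seed Integer seed (mandatory).
#' @return A `design_scenario` object.
#' @export
design_scenario <- function(truth, schedules, n_replicates = 200L,
                            spec = population_spec(), seed) {
  stopifnot(inherits(truth, "trajectory_truth"),
            inherits(spec, "population_spec"))
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  if (!is.list(schedules) || !length(schedules)) {
    abort("`schedules` must be a non-empty list of day vectors.")
  }
  if (is.null(names(schedules)) || any(names(schedules) == "")) {
    names(schedules) <- paste0("schedule_", seq_along(schedules))
  }
  for (nm in names(schedules)) .validate_schedule(schedules[[nm]], nm)
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  structure(list(truth = truth, schedules = schedules,
                 n_replicates = as.integer(n_replicates), spec = spec,
                 seed = as.integer(seed)),
            class = "design_scenario")
}

#' Run a sampling-design simulation
#'
#' For every replicate, one dataset is simulated on the union of all
#' candidate schedules (common random numbers, so schedules are compared on
#' identical data) and each schedule's subset is fitted with the population
#' one-compartment mixed model. Replicate `r` uses seed `seed + r - 1`, so a
#' single-replicate run reproduces one hand-run of simulate-then-fit.
#' Non-convergent fits are counted into `fail_rate` and excluded from the
#' moments, never retried.
#'
#' @param scenario A [design_scenario()].
#' @return A `design_report`: a tibble with one row per schedule x parameter
#'   (`phi1`, `phi2`, `half_life`) holding mean, bias, SD, the
#'   2.5/25/50/75/97.5 percentiles and the non-convergence rate. The raw
#'   per-replicate estimates are attached as attribute `"estimates"`.
#' @export
run_design_sim <- function(scenario) {
  stopifnot(inherits(scenario, "design_scenario"))
  truth <- scenario$truth
  union_days <- sort(unique(unlist(scenario$schedules)))
  truth_union <- truth
  truth_union$schedule <- union_days
  truth_hl <- log(2) / exp(truth$phi3)
  truth_vals <- c(phi1 = truth$phi1, phi2 = truth$phi2,
                  half_life = truth_hl)
  est <- map(seq_len(scenario$n_replicates), function(r) {
    dat <- simulate_trajectories(scenario$spec, truth_union,
                                 seed = scenario$seed + r - 1L)
    imap(scenario$schedules, function(days, nm) {
      sub <- filter(dat, .data$day %in% days)
      fit <- tryCatch(fit_turnover(sub, "one_compartment",
                                   random_effects = "phi3"),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        return(tibble(schedule_id = nm, replicate = r,
                      phi1 = NA_real_, phi2 = NA_real_,
                      half_life = NA_real_))
      }
      tibble(schedule_id = nm, replicate = r,
             phi1 = unname(fit$estimates[["phi1"]]),
             phi2 = unname(fit$estimates[["phi2"]]),
             half_life = fit$half_life$estimate[1])
    }) %>% list_rbind()
  }) %>% list_rbind()

  long <- tidyr::pivot_longer(est, c("phi1", "phi2", "half_life"),
                              names_to = "parameter",
                              values_to = "estimate")
  report <- long %>%
    group_by(.data$schedule_id, .data$parameter) %>%
    summarise(
      truth = unname(truth_vals[.data$parameter[1]]),
      mean = mean(.data$estimate, na.rm = TRUE),
      bias = mean(.data$estimate, na.rm = TRUE) -
        unname(truth_vals[.data$parameter[1]]),
      sd = sd(.data$estimate, na.rm = TRUE),
      p2.5 = quantile(.data$estimate, 0.025, na.rm = TRUE, names = FALSE),
      p25 = quantile(.data$estimate, 0.25, na.rm = TRUE, names = FALSE),
      p50 = quantile(.data$estimate, 0.50, na.rm = TRUE, names = FALSE),
      p75 = quantile(.data$estimate, 0.75, na.rm = TRUE, names = FALSE),
      p97.5 = quantile(.data$estimate, 0.975, na.rm = TRUE, names = FALSE),
      fail_rate = mean(is.na(.data$estimate)),
      .groups = "drop")
  attr(report, "estimates") <- long
  attr(report, "scenario") <- scenario
  class(report) <- c("design_report", class(report))
  report
}

#' Empirical precision of the half-life estimate versus sample size
#'
#' Simulates `n_replicates` experiments at each candidate number of shifted
#' individuals and reports the empirical standard error (SD across
#' replicates) of the estimated population half-life. Under the usual
#' root-n law the SE ratio between two sizes is `sqrt(n2/n1)` — e.g.
#' `sqrt(8) ~ 2.83` between n = 5 and n = 40.
#'
#' @param truth A [trajectory_truth()].
#' @param n_list Integer vector of numbers of shifted individuals (each
#'   >= 2).
#' @param n_replicates Replicates per sample size.
#' @param seed Integer seed (mandatory).
#' @param schedule Optional replacement sampling schedule.
#' @return Tibble with `n`, `se_half_life`, `mean_half_life`, `fail_rate`.
#' @export
compare_sample_sizes <- function(truth, n_list = c(5L, 40L),
                                 n_replicates = 200L, seed,
                                 schedule = NULL) {
  stopifnot(inherits(truth, "trajectory_truth"))
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  if (any(n_list < 2)) abort("Each sample size must be >= 2.")
  if (!is.null(schedule)) {
    .validate_schedule(schedule)
    truth$schedule <- schedule
  }
  rows <- map(seq_along(n_list), function(i) {
    n <- n_list[i]
    spec <- population_spec(n_individuals = n, n_shifted = n)
    hl <- map_dbl(seq_len(n_replicates), function(r) {
      dat <- simulate_trajectories(spec, truth,
                                   seed = seed + (i - 1L) * n_replicates +
                                     r - 1L)
      fit <- tryCatch(fit_turnover(dat, "one_compartment",
                                   random_effects = "phi3"),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) NA_real_ else
        fit$half_life$estimate[1]
    })
    tibble(n = n, se_half_life = sd(hl, na.rm = TRUE),
           mean_half_life = mean(hl, na.rm = TRUE),
           fail_rate = mean(is.na(hl)))
  })
  list_rbind(rows)
}

#' Monte-Carlo half-life recovery under the experimental design
#'
#' Repeatedly simulates a complete diet-switch experiment from a generating
#' truth and refits the population one-compartment mixed model, returning
#' the estimated half-life per replicate (per demographic group when a
#' sex/age fixed effect is requested). Replicate `r` uses `seed + r - 1`.
#'
#' @param truth A [trajectory_truth()].
#' @param spec A [population_spec()] (default 20 shifted individuals).
#' @param n_replicates Number of simulated experiments.
#' @param seed Integer seed (mandatory).
#' @param fixed_effects Passed to [fit_turnover()] (e.g. `"sex"`).
#' @return Tibble with `replicate`, `group`, `estimate` (days); failed fits
#'   yield `NA` estimates.
#' @export
recover_half_life <- function(truth, spec = population_spec(20L, 20L),
                              n_replicates = 200L, seed,
                              fixed_effects = NULL) {
  stopifnot(inherits(truth, "trajectory_truth"))
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  rows <- map(seq_len(n_replicates), function(r) {
    dat <- simulate_trajectories(spec, truth, seed = seed + r - 1L)
    fit <- tryCatch(fit_turnover(dat, "one_compartment",
                                 fixed_effects = fixed_effects,
                                 random_effects = "phi3"),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(tibble(replicate = r, group = NA_character_,
                    estimate = NA_real_))
    }
    tibble(replicate = r, group = fit$half_life$group,
           estimate = fit$half_life$estimate)
  })
  list_rbind(rows)
}
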