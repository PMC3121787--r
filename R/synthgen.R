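# Synthetic-data generators emulating the 40-fox diet-switch experiment:
# population roster, incorporation trajectories with individual
# heterogeneity, flat control trajectories, and discrimination records.

#' The default blood-sampling schedule
#'
#' Days since the diet shift on which blood was drawn in the emulated
#' experiment: 0, 4, 7, 11, 15, 19, 23, 28, 35, 55, 70.
#'
#' @return Numeric vector of days.
#' @export
default_schedule <- function() {
  c(0, 4, 7, 11, 15, 19, 23, 28, 35, 55, 70)
}

#' Population specification for the simulated experiment
#'
#' Defines the roster of simulated individuals: total count, balanced
#' female/male and adult/yearling composition, and how many are shifted to
#' the new (marine) diet versus kept on the terrestrial control diet. The
#' default mirrors the emulated experiment: 40 foxes, 20/20 by sex and by
#' age, 20 shifted and 20 controls, with the shifted group balanced across
#' the four sex x age cells.
#'
#' @param n_individuals Total number of individuals.
#' @param n_shifted Number switched to the new diet (the rest are controls).
#' @param sex_ratio Proportion of females.
#' @param age_ratio Proportion of adults.
#' @return A `population_spec` with the individual `roster` tibble.
#' @export
population_spec <- function(n_individuals = 40L, n_shifted = 20L,
                            sex_ratio = 0.5, age_ratio = 0.5) {
  if (n_individuals < 1 || n_shifted < 0 || n_shifted > n_individuals) {
    abort("Counts must satisfy 0 <= n_shifted <= n_individuals, n >= 1.")
  }
  n_f <- round(n_individuals * sex_ratio)
  n_ad <- round(n_individuals * age_ratio)
  sex <- rep(c("F", "M"), times = c(n_f, n_individuals - n_f))
  # interleave ages within each sex so the cells stay as balanced as the
  # rounding allows
  age <- unlist(lapply(split(seq_len(n_individuals), sex), function(ix) {
    k <- length(ix)
    rep_len(c("adult", "yearling"), k)
  }), use.names = FALSE)
  age <- age[order(order(sex))]  # realign to the sex vector ordering
  roster <- tibble(
    individual_id = sprintf("fox%02d", seq_len(n_individuals)),
    sex = factor(sex, c("F", "M")),
    age = factor(age, c("adult", "yearling"))
  )
  # allocate the shifted arm round-robin across sex x age cells
  cell <- interaction(roster$sex, roster$age)
  ord <- order(stats::ave(seq_len(n_individuals), cell, FUN = seq_along),
               cell)
  roster$group <- "control"
  roster$group[ord[seq_len(n_shifted)]] <- "shifted"
  structure(list(n_individuals = as.integer(n_individuals),
                 n_shifted = as.integer(n_shifted),
                 sex_ratio = sex_ratio, age_ratio = age_ratio,
                 roster = roster),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("Population: %d individuals (%d shifted, %d control)\n",
              x$n_individuals, x$n_shifted,
              x$n_individuals - x$n_shifted))
  print(table(x$roster$sex, x$roster$age))
  invisible(x)
}

#' Generating truth for incorporation trajectories
#'
#' The parameters from which [simulate_trajectories()] draws data for one
#' tissue x isotope: the one-compartment curve of the reference individual
#' (female adult), optional multiplicative sex/age shifts of the rate on the
#' log scale, the SD of the Gaussian individual random effects, the
#' measurement error SD and the sampling schedule. Either `half_life` or
#' `phi3` specifies the rate.
#'
#' @param tissue,isotope Labels written into the generated table.
#' @param phi1,phi2 Asymptotic and initial delta values (permil).
#' @param half_life Reference half-life in days (alternative to `phi3`).
#' @param phi3 Log incorporation rate (alternative to `half_life`).
#' @param sex_effect_phi3 Additive shift of `phi3` for males.
#' @param age_effect_phi3 Additive shift of `phi3` for yearlings.
#' @param re_sd Named SDs of individual Gaussian deviations, e.g.
#'   `c(phi3 = 0.25)`.
#' @param error_sd Measurement error SD (permil), default 0.2.
#' @param schedule Sampling days; strictly increasing, starting at 0.
#' @return A `trajectory_truth` object.
#' @export
trajectory_truth <- function(tissue = "plasma", isotope = "d13C",
                             phi1 = -18.5, phi2 = -24.5,
                             half_life = NULL, phi3 = NULL,
                             sex_effect_phi3 = 0, age_effect_phi3 = 0,
                             re_sd = c(phi3 = 0.25), error_sd = 0.2,
                             schedule = default_schedule()) {
  if (is.null(phi3)) {
    if (is.null(half_life)) abort("Supply `half_life` or `phi3`.")
    phi3 <- phi3_from_half_life(half_life)
  }
  if (error_sd < 0) abort("`error_sd` must be >= 0.")
  if (length(re_sd)) {
    if (is.null(names(re_sd)) ||
        !all(names(re_sd) %in% c("phi1", "phi2", "phi3"))) {
      abort("`re_sd` must be named with parameters among phi1, phi2, phi3.")
    }
    if (any(re_sd < 0)) abort("Random-effect SDs must be >= 0.")
  }
  if (schedule[1] != 0 || is.unsorted(schedule, strictly = TRUE)) {
    abort("`schedule` must be strictly increasing and start at day 0.")
  }
  structure(list(tissue = tissue, isotope = isotope, phi1 = phi1,
                 phi2 = phi2, phi3 = phi3,
                 sex_effect_phi3 = sex_effect_phi3,
                 age_effect_phi3 = age_effect_phi3,
                 re_sd = re_sd, error_sd = error_sd, schedule = schedule),
            class = "trajectory_truth")
}

#' @export
print.trajectory_truth <- function(x, ...) {
  cat(sprintf("Trajectory truth: %s %s\n", x$tissue, x$isotope))
  cat(sprintf("  phi1 %.2f, phi2 %.2f, phi3 %.3f (half-life %.2f d)\n",
              x$phi1, x$phi2, x$phi3, log(2) / exp(x$phi3)))
  cat(sprintf("  re_sd: %s; error_sd %.2f permil; %d sampling days\n",
              paste(names(x$re_sd), round(x$re_sd, 3), sep = "=",
                    collapse = ", "),
              x$error_sd, length(x$schedule)))
  invisible(x)
}

#' Default generating truths for blood tissues
#'
#' One [trajectory_truth()] per tissue x isotope with half-lives matching
#' the fitted estimates the package's simulations are benchmarked against:
#' plasma 9 d (d13C) and 4 d (d15N), blood cells 43 d (d13C) and 40 d
#' (d15N). The delta endpoints are plausible terrestrial-to-marine values
#' (the experiment's diet signatures are not published) and are
#' configurable, not asserted.
#'
#' @return Named list of `trajectory_truth` objects.
#' @export
default_turnover_truths <- function() {
  list(
    plasma_d13C = trajectory_truth("plasma", "d13C", phi1 = -18.5,
                                   phi2 = -24.5, half_life = 9),
    plasma_d15N = trajectory_truth("plasma", "d15N", phi1 = 11.5,
                                   phi2 = 7.0, half_life = 4),
    blood_cells_d13C = trajectory_truth("blood_cells", "d13C", phi1 = -18.0,
                                        phi2 = -24.0, half_life = 43),
    blood_cells_d15N = trajectory_truth("blood_cells", "d15N", phi1 = 11.0,
                                        phi2 = 7.5, half_life = 40)
  )
}

#' Simulate diet-switch incorporation trajectories
#'
#' For every shifted individual in the roster, draws Gaussian parameter
#' deviations per `truth$re_sd`, applies the sex/age shifts of the log rate,
#' evaluates the one-compartment curve at the schedule days and adds i.i.d.
#' Gaussian measurement error. Fully deterministic given `seed`.
#'
#' @param spec A [population_spec()].
#' @param truth A [trajectory_truth()].
#' @param seed Integer seed (mandatory).
#' @param diet Diet label of the post-shift arm (default `"marine"`).
#' @return Long measurement tibble (`individual_id`, `sex`, `age`, `diet`,
#'   `tissue`, `isotope`, `day`, `delta_permil`).
#' @export
simulate_trajectories <- function(spec = population_spec(), truth, seed,
                                  diet = "marine") {
  stopifnot(inherits(spec, "population_spec"),
            inherits(truth, "trajectory_truth"))
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  shifted <- filter(spec$roster, .data$group == "shifted")
  if (!nrow(shifted)) abort("No shifted individuals in the roster.")
  days <- truth$schedule
  re <- function(par) {
    if (par %in% names(truth$re_sd)) truth$re_sd[[par]] else 0
  }
  withr::with_seed(seed, {
    rows <- map(seq_len(nrow(shifted)), function(i) {
      ind <- shifted[i, ]
      p1 <- truth$phi1 + rnorm(1, 0, re("phi1"))
      p2 <- truth$phi2 + rnorm(1, 0, re("phi2"))
      p3 <- truth$phi3 + rnorm(1, 0, re("phi3")) +
        truth$sex_effect_phi3 * (ind$sex == "M") +
        truth$age_effect_phi3 * (ind$age == "yearling")
      mu <- p1 + (p2 - p1) * exp(-exp(p3) * days)
      tibble(individual_id = ind$individual_id, sex = ind$sex,
             age = ind$age, diet = diet, tissue = truth$tissue,
             isotope = truth$isotope, day = days,
             delta_permil = mu + rnorm(length(days), 0, truth$error_sd))
    })
    list_rbind(rows)
  })
}

#' Simulate flat control-group trajectories
#'
#' Control individuals keep their diet, so their expected delta value is
#' constant; measurements are the constant plus Gaussian noise. Feeds
#' [check_equilibrium()].
#'
#' @param spec A [population_spec()]; the control arm of its roster is used.
#' @param delta Named constant delta per isotope, e.g.
#'   `c(d13C = -24, d15N = 7.5)`.
#' @param error_sd Measurement error SD (permil).
#' @param tissue Tissue label.
#' @param schedule Sampling days.
#' @param seed Integer seed (mandatory).
#' @param diet Diet label (default `"terrestrial"`).
#' @return Long measurement tibble.
#' @export
simulate_control_group <- function(spec = population_spec(),
                                   delta = c(d13C = -24, d15N = 7.5),
                                   error_sd = 0.2, tissue = "plasma",
                                   schedule = default_schedule(), seed,
                                   diet = "terrestrial") {
  stopifnot(inherits(spec, "population_spec"))
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  ctrl <- filter(spec$roster, .data$group == "control")
  if (!nrow(ctrl)) abort("No control individuals in the roster.")
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(ctrl, isotope = names(delta),
                               day = schedule)
    grid$tissue <- tissue
    grid$diet <- diet
    grid$delta_permil <- unname(delta[grid$isotope]) +
      rnorm(nrow(grid), 0, error_sd)
    grid[, c("individual_id", "sex", "age", "diet", "tissue", "isotope",
             "day", "delta_permil")]
  })
}

#' Default generating truth for discrimination records
#'
#' Cell means and SDs (permil) for tissue x isotope x sex x age (and diet
#' where the emulated design measured diets separately), patterned on the
#' discrimination table of the emulated experiment. Rows with `sex`/`age`
#' `NA` apply to all individuals (liver, whose sample was too small for
#' demographic cells).
#'
#' @return Tibble with columns `tissue`, `isotope`, `diet`, `sex`, `age`,
#'   `mean`, `sd`.
#' @export
default_discrimination_truth <- function() {
  cell <- function(tissue, isotope, diet, sex, age, mean, sd) {
    tibble(tissue = tissue, isotope = isotope, diet = diet, sex = sex,
           age = age, mean = mean, sd = sd)
  }
  sx <- c("F", "F", "M", "M")
  ag <- c("yearling", "adult", "yearling", "adult")
  bind_rows(
    cell("blood_cells", "d13C", "mix", sx, ag, c(0.28, 0.67, 0.27, 0.57),
         c(0.16, 0.19, 0.13, 0.19)),
    cell("plasma", "d13C", "mix", sx, ag, c(0.59, 0.88, 0.61, 0.80),
         c(0.25, 0.16, 0.25, 0.28)),
    cell("muscle", "d13C", "mix", sx, ag, c(0.23, 0.64, 0.32, 0.31),
         c(0.60, 0.79, 0.85, 0.70)),
    cell("fur", "d13C", "mix", sx, ag, c(1.98, 2.65, 1.89, 2.16),
         c(0.16, 0.22, 0.13, 0.32)),
    cell("nail", "d13C", "mix", sx, ag, c(1.72, 2.94, 1.58, 2.67),
         c(0.32, 0.32, 0.41, 0.58)),
    cell("blood_cells", "d15N", "mix", sx, ag, c(1.55, 2.09, 1.46, 1.93),
         c(0.82, 0.54, 0.85, 0.85)),
    cell("plasma", "d15N", "mix", sx, ag, c(3.41, 3.24, 3.24, 3.08),
         c(0.28, 0.28, 0.28, 0.35)),
    cell("muscle", "d15N", "mix", sx, ag, c(1.83, 1.94, 1.59, 1.92),
         c(0.76, 0.73, 0.85, 0.95)),
    cell("fur", "d15N", "mix", sx, ag, c(2.85, 3.79, 2.77, 4.03),
         c(0.25, 0.38, 0.32, 0.54)),
    cell("nail", "d15N", "mix", sx, ag, c(2.15, 4.70, 2.47, 5.29),
         c(0.32, 0.85, 0.38, 0.82)),
    cell("liver", "d13C", c("marine", "terrestrial"), NA, NA,
         c(0.66, 0.51), c(0.22, 0.22)),
    cell("liver", "d15N", c("marine", "terrestrial"), NA, NA,
         c(1.97, 2.68), c(0.44, 0.28))
  )
}

#' Simulate discrimination records
#'
#' Each record is its cell mean plus an individual-level Gaussian intercept
#' (one draw per individual x isotope, shared across that individual's
#' tissues) plus residual noise with the cell SD. Truth rows with `NA`
#' sex/age match every individual; rows with explicit sex/age match only
#' the roster individuals in that cell.
#'
#' @param truth Truth table as in [default_discrimination_truth()].
#' @param spec A [population_spec()]; all roster individuals are used.
#' @param seed Integer seed (mandatory).
#' @param sd_individual SD of the shared individual intercept (permil).
#' @param cells Optional tibble of requested cells (`tissue`, `isotope`,
#'   `diet`, and optionally `sex`, `age`); every requested cell must have a
#'   truth row, otherwise an error names the missing cell.
#' @return Tibble of discrimination records (`individual_id`, `sex`, `age`,
#'   `tissue`, `diet`, `isotope`, `discrimination`, `lipid_corrected`).
#' @export
simulate_discrimination_dataset <- function(truth =
                                              default_discrimination_truth(),
                                            spec = population_spec(),
                                            seed, sd_individual = 0.1,
                                            cells = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  truth <- as_tibble(truth)
  if (!is.null(cells)) {
    keys <- intersect(c("tissue", "isotope", "diet", "sex", "age"),
                      names(cells))
    missing_cells <- anti_join(as_tibble(cells), truth, by = keys)
    if (nrow(missing_cells)) {
      first <- missing_cells[1, ]
      abort(paste0("No truth entry for cell: ",
                   paste(paste0(keys, "=", unlist(first[keys])),
                         collapse = ", ")))
    }
    truth <- dplyr::semi_join(truth, as_tibble(cells), by = keys)
  }
  roster <- spec$roster
  withr::with_seed(seed, {
    intercepts <- tidyr::expand_grid(
      individual_id = roster$individual_id,
      isotope = unique(truth$isotope)) %>%
      mutate(b = rnorm(n(), 0, sd_individual))
    rows <- map(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      ind <- roster
      if (!is.na(tr$sex)) ind <- filter(ind, .data$sex == tr$sex)
      if (!is.na(tr$age)) ind <- filter(ind, .data$age == tr$age)
      if (!nrow(ind)) return(NULL)
      tibble(individual_id = ind$individual_id, sex = ind$sex,
             age = ind$age, tissue = tr$tissue, diet = tr$diet,
             isotope = tr$isotope,
             discrimination = tr$mean + rnorm(nrow(ind), 0, tr$sd))
    })
    out <- list_rbind(rows[!map_lgl(rows, is.null)])
    out <- left_join(out, intercepts, by = c("individual_id", "isotope"))
    out$discrimination <- out$discrimination + out$b
    out$b <- NULL
    out$lipid_corrected <- out$isotope == "d13C"
    out
  })
}
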