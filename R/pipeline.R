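# Config-driven pipeline commands tying the modules together. Each command
# takes a validated key-value configuration (a list or a YAML file path),
# writes its outputs atomically and drops a manifest sufficient to
# reproduce the run (command, seed, config hash, package version).

.config_keys <- list(
  simulate = list(required = c("seed", "output_dir"),
                  optional = c("n_individuals", "n_shifted", "tissue",
                               "isotope", "phi1", "phi2", "half_life",
                               "sex_effect_phi3", "age_effect_phi3",
                               "re_sd_phi3", "error_sd", "schedule",
                               "diet")),
  fit_turnover = list(required = c("input", "output_dir"),
                      optional = c("tissue", "isotope", "model",
                                   "fixed_effects", "random_effects",
                                   "method", "group", "seed")),
  fit_discrimination = list(required = c("input", "signatures",
                                         "output_dir"),
                            optional = c("isotope", "lipid_correct",
                                         "seed")),
  design_sim = list(required = c("seed", "output_dir", "schedules"),
                    optional = c("n_replicates", "n_individuals", "tissue",
                                 "isotope", "phi1", "phi2", "half_life",
                                 "re_sd_phi3", "error_sd"))
)

#' Read and validate a run configuration
#'
#' @param config A named list or the path of a YAML file.
#' @param command One of `"simulate"`, `"fit_turnover"`,
#'   `"fit_discrimination"`, `"design_sim"`.
#' @return The validated configuration list. Unknown keys are rejected by
#'   name; stochastic commands require a `seed`.
#' @export
read_run_config <- function(config, command = c("simulate", "fit_turnover",
                                                "fit_discrimination",
                                                "design_sim")) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  keys <- .config_keys[[command]]
  unknown <- setdiff(names(config), c(keys$required, keys$optional))
  if (length(unknown)) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  missing_keys <- setdiff(keys$required, names(config))
  if (length(missing_keys)) {
    abort(paste0("Missing configuration key(s): ",
                 paste(missing_keys, collapse = ", ")))
  }
  config
}

.manifest <- function(command, config) {
  cfg <- config[order(names(config))]
  list(command = command,
       seed = config$seed,
       config = cfg,
       config_hash = rlang::hash(cfg),
       package = "isoturn",
       version = as.character(packageVersion("isoturn")))
}

#' Simulate a diet-switch dataset to files
#'
#' Wraps [simulate_trajectories()]: writes `measurements.csv`, a
#' `truth.json` sidecar holding the generating parameters, and
#' `manifest.json`. Identical config + seed produce identical files.
#'
#' @param config Configuration list or YAML path; see
#'   [read_run_config()] (`command = "simulate"`).
#' @return Invisibly, the written file paths.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config, "simulate")
  spec <- population_spec(
    n_individuals = config$n_individuals %||% 40L,
    n_shifted = config$n_shifted %||% 20L)
  truth <- trajectory_truth(
    tissue = config$tissue %||% "plasma",
    isotope = config$isotope %||% "d13C",
    phi1 = config$phi1 %||% -18.5,
    phi2 = config$phi2 %||% -24.5,
    half_life = config$half_life %||% 9,
    sex_effect_phi3 = config$sex_effect_phi3 %||% 0,
    age_effect_phi3 = config$age_effect_phi3 %||% 0,
    re_sd = c(phi3 = config$re_sd_phi3 %||% 0.25),
    error_sd = config$error_sd %||% 0.2,
    schedule = config$schedule %||% default_schedule())
  dat <- simulate_trajectories(spec, truth, seed = config$seed,
                               diet = config$diet %||% "marine")
  dir <- config$output_dir
  paths <- c(measurements = file.path(dir, "measurements.csv"),
             truth = file.path(dir, "truth.json"),
             manifest = file.path(dir, "manifest.json"))
  write_csv_atomic(dat, paths[["measurements"]])
  truth_out <- unclass(truth)
  truth_out$re_sd <- as.list(truth_out$re_sd)
  write_json_atomic(truth_out, paths[["truth"]])
  write_json_atomic(.manifest("simulate", config), paths[["manifest"]])
  invisible(paths)
}

#' Fit turnover models to a measurement file
#'
#' Wraps the kinetics module: reads and validates the input CSV, fits the
#' candidate ladder (the one-compartment model without fixed effects is
#' always included; sex/age fixed effects are added when the covariates
#' vary), selects by AIC with the parsimony rule, and writes the AIC table
#' plus the selected-model report. Input flagged `group: control` is routed
#' to [check_equilibrium()] instead, and the report says so.
#'
#' @param config Configuration list or YAML path
#'   (`command = "fit_turnover"`).
#' @return Invisibly, the written file paths.
#' @export
run_fit_turnover <- function(config) {
  config <- read_run_config(config, "fit_turnover")
  dat <- read_isotope_measurements(config$input)
  if (!is.null(config$tissue)) dat <- filter(dat, .data$tissue ==
                                               config$tissue)
  if (!is.null(config$isotope)) dat <- filter(dat, .data$isotope ==
                                                config$isotope)
  if (!nrow(dat)) abort("No rows left after tissue/isotope filtering.")
  dir <- config$output_dir
  if (identical(config$group, "control")) {
    eq <- check_equilibrium(dat)
    paths <- c(report = file.path(dir, "equilibrium.json"),
               slopes = file.path(dir, "slopes.csv"),
               manifest = file.path(dir, "manifest.json"))
    write_json_atomic(list(mode = "equilibrium_check",
                           selected = eq$selected,
                           delta_aic = eq$delta_aic,
                           aic = eq$aic), paths[["report"]])
    write_csv_atomic(eq$slopes, paths[["slopes"]])
    write_json_atomic(.manifest("fit_turnover", config),
                      paths[["manifest"]])
    return(invisible(paths))
  }
  model <- config$model %||% "one_compartment"
  method <- config$method %||% "nlme"
  random_effects <- config$random_effects %||% "phi3"
  cands <- list(baseline = fit_turnover(dat, model,
                                        random_effects = random_effects,
                                        method = method))
  can_vary <- function(v) v %in% names(dat) &&
    length(unique(dat[[v]])) >= 2
  if (is.null(config$fixed_effects)) {
    if (can_vary("sex")) {
      cands$sex <- fit_turnover(dat, model, fixed_effects = "sex",
                                random_effects = random_effects,
                                method = method)
    }
    if (can_vary("age")) {
      cands$age <- fit_turnover(dat, model, fixed_effects = "age",
                                random_effects = random_effects,
                                method = method)
    }
    if (can_vary("sex") && can_vary("age")) {
      cands$sex_age <- fit_turnover(dat, model,
                                    fixed_effects = c("sex", "age"),
                                    random_effects = random_effects,
                                    method = method)
      cands$sex_x_age <- fit_turnover(
        dat, model, fixed_effects = c("sex", "age", "sex:age"),
        random_effects = random_effects, method = method)
    }
  } else {
    cands$configured <- fit_turnover(
      dat, model, fixed_effects = config$fixed_effects,
      random_effects = random_effects, method = method)
  }
  sel <- select_model(cands)
  paths <- c(aic = file.path(dir, "aic_table.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_csv_atomic(attr(sel, "aic_table"), paths[["aic"]])
  paths <- c(paths, write_fit_report(sel, dir, prefix = "selected_"))
  write_json_atomic(.manifest("fit_turnover", config), paths[["manifest"]])
  invisible(paths)
}

#' Discrimination analysis of a measurement file
#'
#' Computes discrimination records against the diet signatures (lipid
#' correction applied to delta13C where a C:N ratio is present; a missing
#' `c_n_ratio` column is reported and the raw values used), writes the cell
#' summary (tissue x diet x sex x age x isotope), the mixed-model
#' coefficient table per isotope, and — when liver records cover exactly two
#' diets — the Welch two-diet liver comparison.
#'
#' @param config Configuration list or YAML path
#'   (`command = "fit_discrimination"`).
#' @return Invisibly, the written file paths.
#' @export
run_fit_discrimination <- function(config) {
  config <- read_run_config(config, "fit_discrimination")
  dat <- read_isotope_measurements(config$input)
  sig <- read_diet_signatures(config$signatures)
  if (!"c_n_ratio" %in% names(dat)) {
    warn("No `c_n_ratio` column: delta13C left uncorrected.")
  }
  rec <- compute_discrimination(dat, sig,
                                lipid_correct = config$lipid_correct %||%
                                  TRUE)
  dir <- config$output_dir
  summary_tab <- summarize_groups(rec, by = c("tissue", "diet", "sex",
                                              "age", "isotope"))
  paths <- c(summary = file.path(dir, "discrimination_summary.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_csv_atomic(summary_tab, paths[["summary"]])
  isotopes <- config$isotope %||% unique(rec$isotope)
  for (iso in isotopes) {
    fitted <- tryCatch(fit_discrimination_model(rec, isotope = iso),
                       error = function(e) NULL)
    if (!is.null(fitted)) {
      p <- file.path(dir, paste0("model_", iso, ".csv"))
      write_csv_atomic(fitted$coefficients, p)
      paths[[paste0("model_", iso)]] <- p
    }
  }
  liver <- filter(rec, .data$tissue == "liver")
  if (nrow(liver) && length(unique(liver$diet)) == 2) {
    cmp <- map(intersect(isotopes, unique(liver$isotope)), function(iso) {
      tryCatch(compare_diets_two_sample(rec, "liver", iso),
               error = function(e) NULL)
    })
    cmp <- list_rbind(cmp[!map_lgl(cmp, is.null)])
    if (nrow(cmp)) {
      paths[["liver"]] <- file.path(dir, "liver_comparison.csv")
      write_csv_atomic(cmp, paths[["liver"]])
    }
  }
  write_json_atomic(.manifest("fit_discrimination", config),
                    paths[["manifest"]])
  invisible(paths)
}

#' Sampling-design evaluation to files
#'
#' Wraps [run_design_sim()] and writes the report CSV
#' (schedule x parameter rows) plus the run manifest.
#'
#' @param config Configuration list or YAML path
#'   (`command = "design_sim"`).
#' @return Invisibly, the written file paths.
#' @export
run_design_evaluation <- function(config) {
  config <- read_run_config(config, "design_sim")
  truth <- trajectory_truth(
    tissue = config$tissue %||% "plasma",
    isotope = config$isotope %||% "d13C",
    phi1 = config$phi1 %||% -18.5,
    phi2 = config$phi2 %||% -24.5,
    half_life = config$half_life %||% 9,
    re_sd = c(phi3 = config$re_sd_phi3 %||% 0.25),
    error_sd = config$error_sd %||% 0.2)
  spec <- population_spec(
    n_individuals = config$n_individuals %||% 20L,
    n_shifted = config$n_individuals %||% 20L)
  scenario <- design_scenario(truth, config$schedules,
                              n_replicates = config$n_replicates %||% 200L,
                              spec = spec, seed = config$seed)
  report <- run_design_sim(scenario)
  dir <- config$output_dir
  paths <- c(report = file.path(dir, "design_report.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_csv_atomic(as_tibble(report), paths[["report"]])
  write_json_atomic(.manifest("design_sim", config), paths[["manifest"]])
  invisible(paths)
}
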