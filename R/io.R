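# Validated reading and writing of the long-format measurement tables and
# fit reports. CSV dialect: comma separator, "." decimal, UTF-8, LF.

.measurement_schema <- function() {
  list(
    required = c("individual_id", "sex", "age", "diet", "tissue", "isotope",
                 "day", "delta_permil"),
    optional = "c_n_ratio",
    levels = list(sex = c("F", "M"), age = c("adult", "yearling"),
                  diet = c("mix", "terrestrial", "marine"),
                  isotope = c("d13C", "d15N"))
  )
}

#' Validate a long-format isotope measurement table
#'
#' Checks the column set, factor levels (`sex` F/M, `age` adult/yearling,
#' `diet` mix/terrestrial/marine, `isotope` d13C/d15N), non-negative finite
#' days and finite delta values. Offending rows are listed in the error.
#'
#' @param data A data frame to validate.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_measurements <- function(data) {
  data <- as_tibble(data)
  sch <- .measurement_schema()
  missing_cols <- setdiff(sch$required, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  problems <- character()
  for (col in names(sch$levels)) {
    bad <- which(!(as.character(data[[col]]) %in% sch$levels[[col]]))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "`%s` has invalid value(s) in row(s) %s (allowed: %s)",
        col, paste(utils::head(bad, 5), collapse = ", "),
        paste(sch$levels[[col]], collapse = "/")))
    }
  }
  if (!is.numeric(data$day) || any(!is.finite(data$day)) ||
      any(data$day < 0)) {
    bad <- which(!is.finite(data$day) | data$day < 0)
    problems <- c(problems, sprintf(
      "`day` must be finite and >= 0; offending row(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (!is.numeric(data$delta_permil) || any(!is.finite(data$delta_permil))) {
    bad <- which(!is.finite(data$delta_permil))
    problems <- c(problems, sprintf(
      "`delta_permil` must be finite; offending row(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  if ("c_n_ratio" %in% names(data)) {
    bad <- which(!is.na(data$c_n_ratio) & data$c_n_ratio <= 0)
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "`c_n_ratio` must be positive; offending row(s): %s",
        paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (length(problems)) {
    abort(paste0("Measurement table failed validation:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  data
}

#' Read a long-format isotope measurement CSV
#'
#' @param path Path to a UTF-8 CSV with header row and columns
#'   `individual_id, sex, age, diet, tissue, isotope, day, delta_permil`
#'   (plus optional `c_n_ratio`).
#' @return A validated tibble.
#' @export
read_isotope_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_measurements(df)
}

#' Read a diet-signature CSV
#'
#' @param path CSV with columns `diet, isotope, delta_permil` and optional
#'   `c_n_ratio`; one row per diet x isotope.
#' @return A tibble.
#' @export
read_diet_signatures <- function(path) {
  sig <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("diet", "isotope", "delta_permil")
  missing_cols <- setdiff(req, names(sig))
  if (length(missing_cols)) {
    abort(paste0("Diet signature file missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(sig[, c("diet", "isotope")])) {
    abort("Diet signatures must be unique per diet x isotope.")
  }
  as_tibble(sig)
}

# Atomic file write: write to a temp file in the target directory, then
# rename into place.
.write_atomic <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    abort(paste0("Could not write ", path))
  }
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  .write_atomic(function(p) readr::write_csv(df, p, eol = "\n"), path)
}

write_json_atomic <- function(x, path) {
  .write_atomic(function(p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                                 digits = NA, pretty = TRUE),
                path)
}

#' Write a turnover fit report to disk
#'
#' Writes `parameters.csv` (term, estimate, SE, 95% bounds),
#' `half_life.csv`, and `summary.json` (model kind, method, AIC, log
#' likelihood, convergence, sizes) under `dir`, each atomically.
#'
#' @param fit A `turnover_fit`.
#' @param dir Output directory (created if needed).
#' @param prefix Optional file-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_fit_report <- function(fit, dir, prefix = "") {
  stopifnot(inherits(fit, "turnover_fit"))
  paths <- c(
    parameters = file.path(dir, paste0(prefix, "parameters.csv")),
    summary = file.path(dir, paste0(prefix, "summary.json"))
  )
  pars <- rename(fit$parameters, estimate = "estimate", se = "std.error",
                 lower95 = "conf.low", upper95 = "conf.high")
  write_csv_atomic(pars, paths[["parameters"]])
  if (!is.null(fit$half_life)) {
    paths[["half_life"]] <- file.path(dir, paste0(prefix, "half_life.csv"))
    write_csv_atomic(fit$half_life, paths[["half_life"]])
  }
  write_json_atomic(glance(fit), paths[["summary"]])
  invisible(paths)
}
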