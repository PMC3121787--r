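# broom-style tidiers for the fitted objects.

#' Tidy a turnover fit
#'
#' @param x A `turnover_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.turnover_fit <- function(x, ...) {
  x$parameters
}

#' One-row summary of a turnover fit
#'
#' @param x A `turnover_fit`.
#' @param ... Unused.
#' @return Tibble with model kind, method, AIC, log likelihood, parameter
#'   count, residual SD, convergence flag and sizes.
#' @export
glance.turnover_fit <- function(x, ...) {
  tibble(model_kind = x$model_kind, method = x$method, aic = x$aic,
         loglik = x$loglik, n_params = x$n_params, sigma = x$sigma,
         converged = x$converged,
         n_individuals = x$n_individuals,
         n_observations = x$n_observations)
}

#' Tidy a discrimination mixed-model fit
#'
#' @param x A `discrimination_fit`.
#' @param ... Unused.
#' @return The coefficient table of the REML refit of the selected model.
#' @export
tidy.discrimination_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a discrimination fit
#'
#' @param x A `discrimination_fit`.
#' @param ... Unused.
#' @return Tibble with the selected fixed-effect formula, variance
#'   components and sizes.
#' @export
glance.discrimination_fit <- function(x, ...) {
  tibble(selected_formula = x$selected_formula, re_sd = x$re_sd,
         sigma = x$sigma, n_individuals = x$n_individuals,
         n_records = x$n_records)
}

#' Tidy an equilibrium report
#'
#' @param x An `equilibrium_report`.
#' @param ... Unused.
#' @return The AIC comparison table with the selection flag.
#' @export
tidy.equilibrium_report <- function(x, ...) {
  mutate(x$aic, selected = .data$model == x$selected)
}
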