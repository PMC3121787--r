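#' One-compartment incorporation parameters
#'
#' Parameter triple of the single-pool, first-order incorporation model
#' \deqn{\delta(t) = \phi_1 + (\phi_2 - \phi_1) e^{-e^{\phi_3} t}}
#' where `phi1` is the asymptotic delta value (the signature of the new diet
#' plus discrimination), `phi2` the initial value at the moment of the diet
#' shift, and `exp(phi3)` the fractional incorporation rate per day. `phi3`
#' lives on the log scale so the rate is positive by construction and the
#' parameter is unconstrained for optimisation.
#'
#' @param phi1 Asymptotic delta value (permil).
#' @param phi2 Initial delta value (permil).
#' @param phi3 Log of the fractional incorporation rate (log(1/day)).
#' @return An object of class `one_compartment_params`.
#' @examples
#' p <- one_compartment_params(16, 8, log(log(2) / 9))
#' predict_one_compartment(p, c(0, 9, 18))
#' @export
one_compartment_params <- function(phi1, phi2, phi3) {
  for (nm in c("phi1", "phi2", "phi3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("`", nm, "` must be a finite numeric scalar."))
    }
  }
  structure(list(phi1 = phi1, phi2 = phi2, phi3 = phi3),
            class = "one_compartment_params")
}

#' @export
print.one_compartment_params <- function(x, ...) {
  cat("One-compartment incorporation parameters\n")
  cat(sprintf("  phi1 (asymptote): %8.4f permil\n", x$phi1))
  cat(sprintf("  phi2 (initial):   %8.4f permil\n", x$phi2))
  cat(sprintf("  phi3 (log-rate):  %8.4f  -> half-life %.3f days\n",
              x$phi3, half_life_one_compartment(x$phi3)))
  invisible(x)
}

#' Two-compartment incorporation parameters
#'
#' Parameters of the two-pool mixture model
#' \deqn{\delta(t) = \phi_1 + (\phi_2 - \phi_1)\left[p e^{-k_1 t} +
#'   (1-p) e^{-k_2 t}\right]}
#' with pool fraction `p` in \[0, 1\] and positive turnover rates `k1`, `k2`
#' (1/day). The identifiability convention `k1 >= k2` is enforced: if the
#' rates are supplied in the other order they are swapped and `p` is replaced
#' by `1 - p`, which leaves the trajectory unchanged.
#'
#' @param phi1,phi2 Asymptotic and initial delta values (permil).
#' @param p Fraction of the fast pool, in \[0, 1\].
#' @param k1,k2 Turnover rates of the two pools (1/day), both positive.
#' @return An object of class `two_compartment_params`.
#' @export
two_compartment_params <- function(phi1, phi2, p, k1, k2) {
  for (nm in c("phi1", "phi2", "p", "k1", "k2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("`", nm, "` must be a finite numeric scalar."))
    }
  }
  if (p < 0 || p > 1) abort("`p` must lie in [0, 1].")
  if (k1 <= 0 || k2 <= 0) abort("`k1` and `k2` must be positive rates (1/day).")
  if (k1 < k2) {
    tmp <- k1; k1 <- k2; k2 <- tmp
    p <- 1 - p
  }
  structure(list(phi1 = phi1, phi2 = phi2, p = p, k1 = k1, k2 = k2),
            class = "two_compartment_params")
}

#' @export
print.two_compartment_params <- function(x, ...) {
  cat("Two-compartment incorporation parameters\n")
  cat(sprintf("  phi1 %.4f  phi2 %.4f  p %.4f  k1 %.5f  k2 %.5f (1/day)\n",
              x$phi1, x$phi2, x$p, x$k1, x$k2))
  invisible(x)
}

#' Predict the one-compartment incorporation trajectory
#'
#' @param params A [one_compartment_params()] object.
#' @param t Days since the diet shift; non-negative, vectorised.
#' @return Predicted delta values (permil), same length as `t`.
#' @examples
#' p <- one_compartment_params(16, 8, log(log(2) / 9))
#' predict_one_compartment(p, 9) # midpoint: 12
#' @export
predict_one_compartment <- function(params, t) {
  stopifnot(inherits(params, "one_compartment_params"))
  if (!is.numeric(t) || any(!is.finite(t))) abort("`t` must be finite numeric.")
  if (any(t < 0)) abort("`t` must be non-negative (day 0 = diet shift).")
  params$phi1 + (params$phi2 - params$phi1) * exp(-exp(params$phi3) * t)
}

#' Predict the two-compartment incorporation trajectory
#'
#' @param params A [two_compartment_params()] object.
#' @param t Days since the diet shift; non-negative, vectorised.
#' @return Predicted delta values (permil).
#' @export
predict_two_compartment <- function(params, t) {
  stopifnot(inherits(params, "two_compartment_params"))
  if (!is.numeric(t) || any(!is.finite(t))) abort("`t` must be finite numeric.")
  if (any(t < 0)) abort("`t` must be non-negative (day 0 = diet shift).")
  mix <- params$p * exp(-params$k1 * t) + (1 - params$p) * exp(-params$k2 * t)
  params$phi1 + (params$phi2 - params$phi1) * mix
}

#' Isotopic half-life of the one-compartment model
#'
#' Half-life is the time needed to traverse half the gap between the initial
#' and the asymptotic value: `log(2) / exp(phi3)` days.
#'
#' @param phi3 Log incorporation rate, or a [one_compartment_params()] object.
#' @return Half-life in days; strictly decreasing in `phi3`.
#' @examples
#' half_life_one_compartment(0)            # 0.693... days
#' half_life_one_compartment(log(log(2)))  # exactly 1 day
#' @export
half_life_one_compartment <- function(phi3) {
  if (inherits(phi3, "one_compartment_params")) phi3 <- phi3$phi3
  if (!is.numeric(phi3) || any(!is.finite(phi3))) {
    abort("`phi3` must be finite numeric.")
  }
  log(2) / exp(phi3)
}

#' Log incorporation rate for a given half-life
#'
#' Inverse of [half_life_one_compartment()]: `log(log(2) / half_life)`.
#' Convenient for setting simulation truths on the half-life scale.
#'
#' @param half_life Half-life in days, positive.
#' @return The log rate `phi3`.
#' @export
phi3_from_half_life <- function(half_life) {
  if (!is.numeric(half_life) || any(!is.finite(half_life)) ||
      any(half_life <= 0)) {
    abort("`half_life` must be positive and finite.")
  }
  log(log(2) / half_life)
}

#' Isotopic half-life of the two-compartment model
#'
#' The unique time at which the mixture of the two exponential pools has
#' traversed half the gap, i.e. the root of
#' `p exp(-k1 t) + (1 - p) exp(-k2 t) = 1/2`, found by bracketed root search.
#' For degenerate single-pool mixtures (`p` equal to 0 or 1) the closed form
#' `log(2)/k` of the active pool is returned.
#'
#' @param params A [two_compartment_params()] object with `phi1 != phi2`.
#' @return Half-life in days.
#' @export
half_life_two_compartment <- function(params) {
  stopifnot(inherits(params, "two_compartment_params"))
  if (params$phi1 == params$phi2) {
    abort("Half-life is undefined when `phi1 == phi2` (flat trajectory).")
  }
  if (params$p == 1) return(log(2) / params$k1)
  if (params$p == 0) return(log(2) / params$k2)
  g <- function(t) {
    params$p * exp(-params$k1 * t) + (1 - params$p) * exp(-params$k2 * t) - 0.5
  }
  # g decreases from 1/2 at t = 0; by k1 >= k2 the slow-pool half-life bounds
  # the root from above.
  upper <- log(2) / params$k2
  uniroot(g, c(0, upper), tol = 1e-12)$root
}

#' Invert the incorporation curve: time since the diet shift
#'
#' The isotopic clock: given an observed delta value strictly between the
#' initial and asymptotic values, returns the elapsed time
#' `-log((delta_obs - phi1) / (phi2 - phi1)) / exp(phi3)` days. Round-trips
#' exactly with [predict_one_compartment()].
#'
#' @param delta_obs Observed delta value (permil).
#' @param params A [one_compartment_params()] object.
#' @return Days since the diet shift.
#' @examples
#' p <- one_compartment_params(16, 8, log(log(2) / 9))
#' time_since_diet_shift(12, p) # one half-life: 9 days
#' @export
time_since_diet_shift <- function(delta_obs, params) {
  stopifnot(inherits(params, "one_compartment_params"))
  if (!is.numeric(delta_obs) || length(delta_obs) != 1L ||
      !is.finite(delta_obs)) {
    abort("`delta_obs` must be a finite numeric scalar.")
  }
  lo <- min(params$phi1, params$phi2)
  hi <- max(params$phi1, params$phi2)
  gap <- hi - lo
  tol <- 4 * .Machine$double.eps * max(abs(lo), abs(hi), 1)
  if (abs(delta_obs - params$phi1) <= tol) {
    abort("`delta_obs` equals the asymptote: elapsed time is infinite.")
  }
  if (abs(delta_obs - params$phi2) <= tol) return(0)
  if (delta_obs < lo - tol || delta_obs > hi + tol) {
    abort(sprintf(
      "`delta_obs` = %g lies outside the trajectory range [%g, %g].",
      delta_obs, lo, hi))
  }
  frac <- (delta_obs - params$phi1) / (params$phi2 - params$phi1)
  frac <- min(max(frac, .Machine$double.xmin), 1)
  -log(frac) / exp(params$phi3)
}
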