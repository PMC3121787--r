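# AIC-based model selection and interval estimation for turnover fits.

.complexity <- function(fit) {
  cx <- fit$complexity
  if (is.null(cx)) {
    cx <- c(n_params = fit$n_params, n_fixed = length(fit$fixed_effects),
            n_random = length(fit$random_effects))
  }
  as.numeric(cx)
}

#' AIC comparison table for a set of candidate fits
#'
#' @param fits A (preferably named) list of `turnover_fit` objects fitted to
#'   the same data on the same likelihood scale.
#' @return A tibble with one row per candidate: AIC, delta AIC relative to
#'   the best converged candidate, complexity ranks and convergence flags.
#' @export
aic_table <- function(fits) {
  if (!length(fits)) abort("Empty candidate set.")
  nms <- names(fits)
  if (is.null(nms)) nms <- paste0("model_", seq_along(fits))
  tab <- imap(fits, function(f, nm) {
    cx <- .complexity(f)
    tibble(model = nm, aic = f$aic, n_params = cx[1], n_fixed = cx[2],
           n_random = cx[3], converged = f$converged)
  }) %>% list_rbind()
  tab$model <- nms
  best <- suppressWarnings(min(tab$aic[tab$converged], na.rm = TRUE))
  tab$delta_aic <- tab$aic - best
  arrange(tab, .data$aic)
}

#' Select a model by AIC with a parsimony tie-break
#'
#' Among converged candidates, the minimum-AIC model wins unless other
#' candidates lie within `delta_aic` units of the minimum; in that case the
#' simplest of those is returned, complexity being ranked lexicographically
#' by (number of free parameters, number of fixed effects, number of random
#' effects).
#'
#' @param fits List of `turnover_fit` (or compatible) objects sharing data
#'   and likelihood scale.
#' @param delta_aic Cut-off below which models are considered equivalent
#'   (default 2).
#' @return The selected fit, with the comparison table attached as
#'   attribute `"aic_table"`.
#' @export
select_model <- function(fits, delta_aic = 2) {
  if (!length(fits)) abort("Empty candidate set.")
  if (is.null(names(fits))) names(fits) <- paste0("model_", seq_along(fits))
  conv <- map_lgl(fits, function(f) isTRUE(f$converged) && is.finite(f$aic))
  if (!any(conv)) abort("All candidate fits failed to converge.")
  tab <- aic_table(fits)
  cand <- fits[conv]
  aics <- map_dbl(cand, "aic")
  within <- aics <= min(aics) + delta_aic
  pool <- cand[within]
  cx <- t(vapply(pool, .complexity, numeric(3)))
  ord <- order(cx[, 1], cx[, 2], cx[, 3], map_dbl(pool, "aic"))
  sel <- pool[[ord[1]]]
  attr(sel, "aic_table") <- mutate(tab, selected = .data$model ==
                                     names(pool)[ord[1]])
  sel
}

# Simulate one dataset from a fitted population one-compartment model:
# same individuals, covariates and days; fresh random effects and residuals.
.simulate_from_fit <- function(fit) {
  data <- fit$data
  est <- fit$estimates
  fe <- fit$fixed_effects
  # phi3 linear predictor per individual
  if (length(fe) == 0) {
    nm3 <- if ("phi3" %in% names(est)) "phi3" else "phi3.(Intercept)"
    lp3 <- setNames(rep(est[[nm3]], length(levels(data$individual_id))),
                    levels(data$individual_id))
  } else {
    ind <- distinct(data, .data$individual_id, .keep_all = TRUE)
    X <- stats::model.matrix(.fe_formula(fe), ind)
    idx <- grep("^phi3", names(est))
    lp3 <- setNames(drop(X %*% est[idx]), as.character(ind$individual_id))
  }
  p1 <- est[[grep("^phi1", names(est), value = TRUE)[1]]]
  p2 <- est[[grep("^phi2", names(est), value = TRUE)[1]]]
  re3 <- if ("phi3" %in% names(fit$re_sd)) fit$re_sd[["phi3"]] else 0
  re1 <- if ("phi1" %in% names(fit$re_sd)) fit$re_sd[["phi1"]] else 0
  re2 <- if ("phi2" %in% names(fit$re_sd)) fit$re_sd[["phi2"]] else 0
  ids <- levels(data$individual_id)
  b3 <- setNames(rnorm(length(ids), 0, re3), ids)
  b1 <- setNames(rnorm(length(ids), 0, re1), ids)
  b2 <- setNames(rnorm(length(ids), 0, re2), ids)
  id <- as.character(data$individual_id)
  mu <- (p1 + b1[id]) +
    ((p2 + b2[id]) - (p1 + b1[id])) * exp(-exp(lp3[id] + b3[id]) * data$day)
  out <- data
  out$delta_permil <- mu + rnorm(nrow(data), 0, fit$sigma)
  out
}

#' Confidence intervals for turnover parameters and half-lives
#'
#' Wald intervals are computed on the fitting scale and the half-life
#' interval is obtained by the monotone transform of the log-rate interval.
#' The parametric bootstrap resimulates complete datasets from the fitted
#' model (fresh individual random effects and residual noise), refits, and
#' reports percentile intervals; a seed is mandatory so the resampling is
#' reproducible.
#'
#' @param fit A converged `turnover_fit`.
#' @param method `"wald"` or `"parametric_bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed; required for the bootstrap.
#' @return A list with tibbles `parameters` and `half_life`, plus metadata.
#' @export
confidence_intervals <- function(fit, method = c("wald",
                                                 "parametric_bootstrap"),
                                 level = 0.95, n_boot = 1000L, seed = NULL) {
  method <- match.arg(method)
  if (!isTRUE(fit$converged)) {
    abort("Confidence intervals require a converged fit.")
  }
  if (method == "wald") {
    z <- qnorm((1 + level) / 2)
    pars <- mutate(fit$parameters,
                   conf.low = .data$estimate - z * .data$std.error,
                   conf.high = .data$estimate + z * .data$std.error)
    hl <- NULL
    if (!is.null(fit$half_life)) {
      hl <- fit$half_life %>%
        mutate(lower = log(2) / exp(.data$log_rate + z * .data$log_rate_se),
               upper = log(2) / exp(.data$log_rate - z * .data$log_rate_se))
    }
    return(list(parameters = pars, half_life = hl, method = "wald",
                level = level))
  }
  if (is.null(seed)) {
    abort("`seed` is mandatory for the parametric bootstrap.")
  }
  if (fit$model_kind != "one_compartment" || is.null(fit$data)) {
    abort("Parametric bootstrap is implemented for one-compartment fits.")
  }
  boot <- withr::with_seed(seed, {
    map(seq_len(n_boot), function(b) {
      sim <- .simulate_from_fit(fit)
      ref <- tryCatch(
        if (fit$n_individuals > 1 && !identical(fit$method, "pooled_nls")) {
          fit_turnover(sim, model = "one_compartment",
                       fixed_effects = fit$fixed_effects,
                       random_effects = fit$random_effects,
                       method = if (identical(fit$method, "two_stage"))
                         "two_stage" else "nlme")
        } else {
          fit_turnover_individual(sim, "one_compartment")
        },
        error = function(e) NULL)
      if (is.null(ref) || !ref$converged) return(NULL)
      list(est = ref$estimates, hl = ref$half_life)
    })
  })
  ok <- !map_lgl(boot, is.null)
  if (sum(ok) < 2) abort("Parametric bootstrap: too few converged refits.")
  alpha <- (1 - level) / 2
  est_mat <- do.call(rbind, map(boot[ok], "est"))
  qs <- apply(est_mat, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  pars <- tibble(term = colnames(est_mat),
                 estimate = fit$parameters$estimate[
                   match(colnames(est_mat), fit$parameters$term)],
                 conf.low = qs[1, ], conf.high = qs[2, ])
  hl <- NULL
  if (!is.null(fit$half_life)) {
    hls <- map(boot[ok], function(b) b$hl$estimate)
    hl_mat <- do.call(rbind, hls)
    hq <- apply(hl_mat, 2, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    hl <- tibble(group = fit$half_life$group,
                 estimate = fit$half_life$estimate,
                 lower = hq[1, ], upper = hq[2, ])
  }
  list(parameters = pars, half_life = hl, method = "parametric_bootstrap",
       level = level, n_boot = n_boot, n_converged = sum(ok), seed = seed)
}

#' Check isotopic equilibrium of control trajectories
#'
#' Control individuals that never changed diet should show flat isotope
#' trajectories. This fits a constant-mean model and the one-compartment
#' incorporation model to the pooled data, compares them by AIC under the
#' same parsimony rule as [select_model()] (within 2 AIC units the simpler,
#' constant model wins), and reports per-individual linear slopes as a
#' diagnostic.
#'
#' @param data Table with columns `day`, `delta_permil`, and optionally
#'   `individual_id` (used for the slope diagnostic).
#' @param delta_aic Parsimony cut-off (default 2).
#' @return An `equilibrium_report` list: `selected` ("constant" or
#'   "one_compartment"), `delta_aic` (AIC constant minus AIC kinetic), an
#'   `aic` tibble and a `slopes` tibble.
#' @export
check_equilibrium <- function(data, delta_aic = 2) {
  data <- as_tibble(data)
  if (!all(c("day", "delta_permil") %in% names(data))) {
    abort("`data` needs columns `day` and `delta_permil`.")
  }
  if (length(unique(data$day)) < 3) {
    abort("Equilibrium check needs >= 3 distinct sampling days.")
  }
  n <- nrow(data)
  rss_const <- sum((data$delta_permil - mean(data$delta_permil))^2)
  ll_const <- .gaussian_ll(rss_const, n)
  aic_const <- -2 * ll_const + 2 * 2  # mean + sigma

  oc <- tryCatch(fit_turnover_individual(data, "one_compartment"),
                 error = function(e) NULL)
  if (!is.null(oc) && oc$converged) {
    aic_oc <- oc$aic
  } else {
    aic_oc <- Inf
  }
  # parsimony: the kinetic model must beat the constant one by > delta_aic
  selected <- if (aic_const <= aic_oc + delta_aic) "constant" else
    "one_compartment"
  slopes <- NULL
  if ("individual_id" %in% names(data)) {
    slopes <- data %>%
      group_by(.data$individual_id) %>%
      summarise(slope = {
        f <- lm(delta_permil ~ day, data = pick(day, delta_permil))
        coef(f)[["day"]]
      }, .groups = "drop")
  } else {
    f <- lm(delta_permil ~ day, data = data)
    slopes <- tibble(individual_id = "all", slope = coef(f)[["day"]])
  }
  structure(list(
    selected = selected,
    delta_aic = aic_const - aic_oc,
    aic = tibble(model = c("constant", "one_compartment"),
                 aic = c(aic_const, aic_oc),
                 n_params = c(2L, 4L)),
    slopes = slopes,
    kinetic_fit = oc
  ), class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Equilibrium check of control trajectories\n")
  cat(sprintf("  selected model: %s (AIC constant - kinetic = %.2f)\n",
              x$selected, x$delta_aic))
  cat(sprintf("  mean per-individual slope: %.4g permil/day\n",
              mean(x$slopes$slope)))
  invisible(x)
}
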