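# Individual and population fitting of the incorporation models.

test_that("noiseless individual data are recovered to optimizer tolerance", {
  d <- noiseless_trajectory()
  fit <- fit_turnover_individual(d)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[["phi1"]]), 16, tolerance = 1e-6)
  expect_equal(unname(fit$estimates[["phi2"]]), 8, tolerance = 1e-6)
  expect_equal(unname(fit$estimates[["phi3"]]), log(log(2) / 9),
               tolerance = 1e-6)
  expect_equal(fit$half_life$estimate, 9, tolerance = 1e-6)
  # AIC recomputable from stored fields
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
})

test_that("individual NLS agrees with a brute-force grid oracle", {
  days <- c(0, 5, 10, 20, 40, 70)
  truth <- one_compartment_params(16.3, 8.2, -2.5)
  d <- noiseless_trajectory(truth, days)
  fit <- fit_turnover_individual(d)
  # independent oracle: dense grid search over the parameter box
  grid1 <- seq(15.3, 17.3, by = 0.1)
  grid2 <- seq(7.2, 9.2, by = 0.1)
  grid3 <- seq(-3.0, -2.0, by = 0.05)
  best <- c(NA, NA, NA); best_rss <- Inf
  for (a in grid1) for (b in grid2) for (cc in grid3) {
    rss <- sum((d$delta_permil - (a + (b - a) * exp(-exp(cc) * days)))^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(a, b, cc) }
  }
  expect_lt(abs(fit$estimates[["phi1"]] - best[1]), 0.1)
  expect_lt(abs(fit$estimates[["phi2"]] - best[2]), 0.1)
  expect_lt(abs(fit$estimates[["phi3"]] - best[3]), 0.05)
})

test_that("constant trajectories flag the rate as unidentifiable", {
  d <- tibble::tibble(day = default_schedule(), delta_permil = 5)
  fit <- fit_turnover_individual(d)
  expect_true(fit$converged)
  expect_false(fit$rate_identifiable)
  expect_equal(unname(fit$estimates[["phi1"]]), 5)
  expect_equal(unname(fit$estimates[["phi2"]]), 5)
  expect_null(fit$half_life)
})

test_that("too few sampling days is an explicit error", {
  d <- tibble::tibble(day = c(0, 4, 7), delta_permil = c(8, 10, 11))
  expect_error(fit_turnover_individual(d), ">= 4 distinct")
  d6 <- noiseless_trajectory(days = c(0, 4, 7, 11, 15))
  expect_error(fit_turnover_individual(d6, "two_compartment"),
               ">= 6 distinct")
})

test_that("two-compartment fit to one-compartment data shows overparametrization", {
  set.seed(5)
  d <- noiseless_trajectory()
  d$delta_permil <- d$delta_permil + rnorm(nrow(d), 0, 0.05)
  fit <- fit_turnover_individual(d, "two_compartment")
  # either non-convergence or a boundary mixture: both diagnose one pool
  p_hat <- fit$estimates[["p"]]
  k_ratio <- fit$estimates[["k2"]] / fit$estimates[["k1"]]
  expect_true(!fit$converged || p_hat < 0.01 || p_hat > 0.99 ||
                k_ratio > 0.99)
})

test_that("two-compartment fit recovers genuinely two-pool data", {
  truth <- two_compartment_params(16, 8, p = 0.6, k1 = 0.3, k2 = 0.02)
  days <- c(0, 2, 4, 7, 11, 15, 19, 23, 28, 35, 45, 55, 70, 90)
  d <- tibble::tibble(day = days,
                      delta_permil = predict_two_compartment(truth, days))
  set.seed(6)
  fit <- fit_turnover_individual(d, "two_compartment")
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[["p"]]), 0.6, tolerance = 0.01)
  expect_equal(unname(fit$estimates[["k1"]]), 0.3, tolerance = 0.01)
  expect_equal(unname(fit$estimates[["k2"]]), 0.02, tolerance = 0.01)
})

test_that("population mixed fit recovers truth and nests the pooled fit", {
  truth <- plasma_c_truth()
  spec <- population_spec(20, 20)
  dat <- simulate_trajectories(spec, truth, seed = 301)
  fit <- fit_turnover(dat)
  expect_true(fit$converged)
  expect_equal(fit$half_life$estimate, 9, tolerance = 0.15)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params,
               tolerance = 1e-8)
  expect_gt(fit$re_sd[["phi3"]], 0.1)

  # zero-heterogeneity data: the mixed fit collapses onto pooled NLS
  truth0 <- plasma_c_truth(re_sd = c(phi3 = 0))
  dat0 <- simulate_trajectories(spec, truth0, seed = 302)
  mixed0 <- fit_turnover(dat0)
  pooled <- fit_turnover(dat0, random_effects = NULL)
  expect_identical(pooled$method, "pooled_nls")
  expect_equal(unname(mixed0$estimates[["phi3"]]),
               unname(pooled$estimates[["phi3"]]), tolerance = 0.01)
  expect_lt(mixed0$re_sd[["phi3"]], 0.05)
})

test_that("two-stage estimator cross-checks the joint mixed fit", {
  dat <- simulate_trajectories(population_spec(20, 20), plasma_c_truth(),
                               seed = 303)
  joint <- fit_turnover(dat, method = "nlme")
  two <- fit_turnover(dat, method = "two_stage")
  expect_true(two$converged)
  expect_equal(unname(two$estimates[["phi3"]]),
               unname(joint$estimates[["phi3"]]), tolerance = 0.1)
  expect_equal(two$half_life$estimate, joint$half_life$estimate,
               tolerance = 0.15)
  expect_equal(two$re_sd[["phi3"]], joint$re_sd[["phi3"]],
               tolerance = 0.15)
})

test_that("sex effects on the log rate translate into group half-lives", {
  truth <- trajectory_truth("blood_cells", "d15N", phi1 = 11, phi2 = 7.5,
                            half_life = 46,
                            sex_effect_phi3 = log(46 / 36))
  dat <- simulate_trajectories(population_spec(20, 20), truth, seed = 304)
  fit <- fit_turnover(dat, fixed_effects = "sex")
  expect_true(fit$converged)
  hl <- fit$half_life
  expect_identical(hl$group, c("sex=F", "sex=M"))
  diff_fm <- hl$estimate[1] - hl$estimate[2]
  expect_gt(diff_fm, 2)  # females markedly slower in this draw
  expect_error(fit_turnover(dat, fixed_effects = "colour"), "Unknown fixed")
})

test_that("Wald coverage of the population half-life is close to nominal", {
  truth <- plasma_c_truth()
  spec <- population_spec(20, 20)
  hits <- vapply(1:200, function(r) {
    dat <- simulate_trajectories(spec, truth, seed = 5000 + r)
    fit <- tryCatch(fit_turnover(dat), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NA)
    fit$half_life$lower[1] <= 9 && 9 <= fit$half_life$upper[1]
  }, logical(1))
  cover <- mean(hits, na.rm = TRUE)
  expect_gte(cover, 0.90)
  expect_lte(cover, 1.00)
})
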