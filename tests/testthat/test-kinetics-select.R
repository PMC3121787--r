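# Model selection, confidence intervals and the equilibrium check.

test_that("selection prefers the simplest model within the AIC cut-off", {
  complex <- stub_fit(100.0, n_params = 6, n_fixed = 2)
  simple <- stub_fit(101.5, n_params = 4, n_fixed = 0)
  sel <- select_model(list(complex = complex, simple = simple))
  expect_equal(sel$complexity[["n_params"]], 4)
  tab <- attr(sel, "aic_table")
  expect_true(tab$selected[tab$model == "simple"])

  # clear winner outside the cut-off
  sel2 <- select_model(list(good = stub_fit(100, 6, 2),
                            bad = stub_fit(105, 4, 0)))
  expect_equal(sel2$aic, 100)

  # single candidate returns itself
  only <- stub_fit(50, 4)
  expect_equal(select_model(list(only))$aic, 50)

  # non-converged candidates are excluded; all failing is an error
  sel3 <- select_model(list(a = stub_fit(90, 4, converged = FALSE),
                            b = stub_fit(95, 4)))
  expect_equal(sel3$aic, 95)
  expect_error(select_model(list(stub_fit(1, 4, converged = FALSE))),
               "converge")
  expect_error(select_model(list()), "Empty")
})

test_that("ties break lexicographically on (params, fixed, random)", {
  a <- stub_fit(100.0, n_params = 5, n_fixed = 1, n_random = 1)
  b <- stub_fit(100.5, n_params = 5, n_fixed = 0, n_random = 2)
  sel <- select_model(list(a = a, b = b))
  expect_identical(attr(sel, "aic_table")$model[
    attr(sel, "aic_table")$selected], "b")
})

test_that("Wald half-life interval is the monotone image of the phi3 interval", {
  dat <- simulate_trajectories(population_spec(20, 20), plasma_c_truth(),
                               seed = 401)
  fit <- fit_turnover(dat)
  ci <- confidence_intervals(fit, "wald")
  hl <- ci$half_life
  z <- qnorm(0.975)
  expect_equal(hl$lower,
               log(2) / exp(hl$log_rate + z * hl$log_rate_se))
  expect_equal(hl$upper,
               log(2) / exp(hl$log_rate - z * hl$log_rate_se))
  expect_true(all(hl$lower < hl$estimate & hl$estimate < hl$upper))
  # worked mapping for a fixed phi3 interval
  expect_equal(log(2) / exp(-2.2), 6.2556, tolerance = 1e-4)
  expect_equal(log(2) / exp(-2.9), 12.5973, tolerance = 1e-4)
})

test_that("parametric bootstrap requires a seed, is reproducible, shrinks with noise", {
  dat <- simulate_trajectories(population_spec(10, 10), plasma_c_truth(),
                               seed = 402)
  fit <- fit_turnover(dat)
  expect_error(confidence_intervals(fit, "parametric_bootstrap",
                                    n_boot = 5), "seed")
  b1 <- confidence_intervals(fit, "parametric_bootstrap", n_boot = 20,
                             seed = 11)
  b2 <- confidence_intervals(fit, "parametric_bootstrap", n_boot = 20,
                             seed = 11)
  expect_equal(b1$half_life, b2$half_life)
  expect_true(b1$half_life$lower < b1$half_life$upper)

  # near-zero noise: interval width collapses towards zero
  quiet <- plasma_c_truth(re_sd = c(phi3 = 0), error_sd = 1e-4)
  dq <- simulate_trajectories(population_spec(5, 5), quiet, seed = 403)
  fq <- fit_turnover(dq)
  bq <- confidence_intervals(fq, "parametric_bootstrap", n_boot = 20,
                             seed = 12)
  expect_lt(bq$half_life$upper - bq$half_life$lower, 0.02)
})

test_that("flat control data select the constant model; trends select the kinetic one", {
  ctrl <- simulate_control_group(population_spec(40, 20),
                                 delta = c(d13C = 7), error_sd = 0.2,
                                 seed = 404)
  eq <- check_equilibrium(ctrl)
  expect_identical(eq$selected, "constant")
  expect_lt(max(abs(eq$slopes$slope)), 0.05)

  trend <- simulate_trajectories(population_spec(10, 10),
                                 plasma_c_truth(), seed = 405)
  eq2 <- check_equilibrium(trend)
  expect_identical(eq2$selected, "one_compartment")
  expect_gt(eq2$delta_aic, 2)

  expect_error(check_equilibrium(
    tibble::tibble(day = c(0, 4), delta_permil = c(1, 1))), ">= 3")
})

test_that("zero-noise constant data favour the constant model by the parameter penalty", {
  d <- tibble::tibble(individual_id = "fox01", day = default_schedule(),
                      delta_permil = 7)
  eq <- check_equilibrium(d)
  expect_identical(eq$selected, "constant")
  # equal (floored) likelihoods: AIC difference is twice the extra
  # parameter count of the kinetic model
  expect_lte(eq$delta_aic, -2)
  expect_equal(eq$delta_aic, -4)
})
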