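# Synthetic-data generators: design structure, determinism, fidelity.

test_that("the default roster mirrors the experimental design", {
  spec <- population_spec()
  r <- spec$roster
  expect_equal(nrow(r), 40L)
  expect_equal(sum(r$sex == "F"), 20L)
  expect_equal(sum(r$age == "adult"), 20L)
  expect_equal(sum(r$group == "shifted"), 20L)
  # shifted arm balanced across the four demographic cells
  tab <- table(r$sex[r$group == "shifted"], r$age[r$group == "shifted"])
  expect_true(all(tab == 5))
  expect_error(population_spec(10, 11), "n_shifted")
})

test_that("trajectory truths validate their inputs", {
  expect_error(trajectory_truth(half_life = 9, schedule = c(1, 2, 3, 4)),
               "day 0")
  expect_error(trajectory_truth(half_life = 9, error_sd = -1), "error_sd")
  expect_error(trajectory_truth(half_life = 9, re_sd = c(zeta = 1)),
               "phi1")
  expect_error(trajectory_truth(half_life = NULL, phi3 = NULL),
               "half_life")
  tr <- trajectory_truth(half_life = 9)
  expect_equal(log(2) / exp(tr$phi3), 9)
})

test_that("simulation is exact without noise and bit-identical under a seed", {
  quiet <- plasma_c_truth(re_sd = c(phi3 = 0), error_sd = 0)
  spec <- population_spec(6, 6)
  d <- simulate_trajectories(spec, quiet, seed = 601)
  p <- one_compartment_params(-18.5, -24.5, quiet$phi3)
  expect_equal(d$delta_permil, predict_one_compartment(p, d$day))

  t1 <- simulate_trajectories(spec, plasma_c_truth(), seed = 602)
  t2 <- simulate_trajectories(spec, plasma_c_truth(), seed = 602)
  expect_identical(t1, t2)
  t3 <- simulate_trajectories(spec, plasma_c_truth(), seed = 603)
  expect_false(identical(t1$delta_permil, t3$delta_permil))
  expect_error(simulate_trajectories(spec, plasma_c_truth()), "seed")
})

test_that("generated tables pass the long-format schema", {
  d <- simulate_trajectories(population_spec(5, 5), plasma_c_truth(),
                             seed = 604)
  expect_silent(validate_measurements(d))
  ctrl <- simulate_control_group(population_spec(6, 3), seed = 605)
  expect_silent(validate_measurements(ctrl))
})

test_that("the dispersion at a fixed day matches the delta-method oracle", {
  truth <- plasma_c_truth(schedule = c(0, 15))
  big <- population_spec(10000, 10000)
  d <- simulate_trajectories(big, truth, seed = 606)
  obs_sd <- sd(d$delta_permil[d$day == 15])
  k <- exp(truth$phi3)
  dy_dphi3 <- (truth$phi2 - truth$phi1) * exp(-k * 15) * (-k * 15)
  pred_sd <- sqrt(truth$error_sd^2 + dy_dphi3^2 * 0.25^2)
  expect_equal(obs_sd, pred_sd, tolerance = 0.05)
})

test_that("control trajectories are flat and close the loop with the equilibrium check", {
  spec <- population_spec(10, 5)
  quiet <- simulate_control_group(spec, delta = c(d15N = 7),
                                  error_sd = 0, seed = 607)
  expect_true(all(quiet$delta_permil == 7))
  noisy <- simulate_control_group(spec, delta = c(d15N = 7), seed = 608)
  eq <- check_equilibrium(noisy)
  expect_identical(eq$selected, "constant")
})

test_that("discrimination records are cell means plus shared intercept plus noise", {
  truth <- default_discrimination_truth()
  exact <- dplyr::mutate(truth, sd = 0)
  rec <- simulate_discrimination_dataset(exact, population_spec(8, 4),
                                         seed = 609, sd_individual = 0)
  rec <- dplyr::mutate(rec, sex = as.character(sex),
                       age = as.character(age))
  joined <- dplyr::left_join(
    rec, truth,
    by = c("tissue", "isotope", "diet", "sex", "age"))
  demog <- joined[!is.na(joined$mean), ]
  expect_gt(nrow(demog), 0)
  expect_equal(demog$discrimination, demog$mean)

  # the default truth carries the emulated design's demographic cell means
  expect_equal(truth$mean[truth$tissue == "nail" &
                            truth$isotope == "d15N" &
                            truth$sex == "M" & truth$age == "adult"], 5.29)

  # moments converge to the specified truth at large n
  one_cell <- tibble::tibble(tissue = "plasma", isotope = "d15N",
                             diet = "mix", sex = NA_character_,
                             age = NA_character_, mean = 3.2, sd = 0.3)
  bigrec <- simulate_discrimination_dataset(one_cell,
                                            population_spec(10000, 0),
                                            seed = 610,
                                            sd_individual = 0.1)
  tot_sd <- sqrt(0.3^2 + 0.1^2)
  expect_equal(mean(bigrec$discrimination), 3.2,
               tolerance = 3 * tot_sd / sqrt(10000))
  expect_equal(sd(bigrec$discrimination), tot_sd, tolerance = 0.02)

  # missing requested cell is named
  expect_error(simulate_discrimination_dataset(
    one_cell, population_spec(4, 2), seed = 611,
    cells = tibble::tibble(tissue = "fur", isotope = "d15N",
                           diet = "mix")), "fur")
})
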