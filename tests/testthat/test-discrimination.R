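# Discrimination factors, lipid normalization, summaries and group models.

test_that("lipid normalization behaves as specified", {
  # fixed point of the default normalization
  expect_equal(lipid_normalize_d13c(-20, 3.32 / 0.99), -20)
  expect_equal(lipid_normalize_d13c(-20, 4), -19.36)
  expect_identical(lipid_normalize_d13c(-20, NULL), -20)
  expect_equal(lipid_normalize_d13c(-20, NA_real_), -20)
  expect_error(lipid_normalize_d13c(-20, -1), "positive")
  # strictly increasing in C:N
  cn <- seq(2, 8, by = 0.5)
  expect_true(all(diff(lipid_normalize_d13c(-20, cn)) > 0))
})

test_that("discrimination is the tissue-diet difference, translation-invariant", {
  expect_equal(discrimination_factor(10, 7.4), 2.6)
  expect_equal(discrimination_factor(5, 5), 0)
  expect_equal(discrimination_factor(-21, -20), -1)
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(1); b <- rnorm(1); shift <- rnorm(1, 0, 50)
    expect_equal(discrimination_factor(a + shift, b + shift),
                 discrimination_factor(a, b), tolerance = 1e-9)
  }
})

test_that("compute_discrimination joins signatures and tracks lipid correction", {
  dat <- tibble::tibble(
    individual_id = c("a", "a", "b"), sex = "F", age = "adult",
    diet = "marine", tissue = "plasma",
    isotope = c("d15N", "d13C", "d13C"),
    day = 70, delta_permil = c(12, -19, -19),
    c_n_ratio = c(NA, 4, NA))
  sig <- tibble::tibble(diet = "marine", isotope = c("d15N", "d13C"),
                        delta_permil = c(11, -18))
  rec <- compute_discrimination(dat, sig)
  expect_equal(rec$discrimination[1], 1)                 # d15N untouched
  expect_equal(rec$discrimination[2], -19 - 3.32 + 3.96 - (-18))
  expect_equal(rec$discrimination[3], -1)                # no C:N: raw
  expect_identical(rec$lipid_corrected, c(FALSE, TRUE, FALSE))
  # disabling the correction reproduces raw differences exactly
  raw <- compute_discrimination(dat, sig, lipid_correct = FALSE)
  expect_equal(raw$discrimination[2], -1)
  # missing signature is named
  expect_error(compute_discrimination(
    dplyr::mutate(dat, diet = "mix"), sig), "mix")
})

test_that("group summaries report mean, n-1 SD and n deterministically", {
  rec <- tibble::tibble(tissue = "plasma", diet = "mix",
                        discrimination = c(2, 3))
  s <- summarize_groups(rec, by = c("tissue", "diet"))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sqrt(0.5), tolerance = 1e-6)
  expect_equal(s$n, 2L)
  one <- summarize_groups(rec[1, ], by = "tissue")
  expect_true(is.na(one$sd))
  expect_error(summarize_groups(rec, by = "planet"), "Unknown grouping")

  # group sizes partition the records
  set.seed(31)
  many <- tibble::tibble(tissue = sample(c("fur", "nail"), 57, TRUE),
                         discrimination = rnorm(57))
  expect_equal(sum(summarize_groups(many, by = "tissue")$n), 57L)
})

test_that("overall means collapse demographic cells, weighted or not", {
  cells <- tidyr::expand_grid(sex = c("F", "M"),
                              age = c("adult", "yearling"), i = 1:5)
  cells$tissue <- "blood_cells"
  cells$isotope <- "d13C"
  means <- c(`F.adult` = 0.67, `F.yearling` = 0.28,
             `M.adult` = 0.57, `M.yearling` = 0.27)
  cells$discrimination <- means[paste(cells$sex, cells$age, sep = ".")]
  ov <- overall_means(cells, weighted = FALSE)
  expect_equal(ov$mean, 0.4475)
  # equal cell sizes: weighted equals unweighted
  expect_equal(overall_means(cells, weighted = TRUE)$mean, 0.4475)
})

test_that("mixed-model ladder recovers a pure diet effect and drops the rest", {
  truth <- tibble::tibble(tissue = "blood_cells", isotope = "d15N",
                          diet = c("marine", "terrestrial", "mix"),
                          sex = NA_character_, age = NA_character_,
                          mean = c(0.4, 1.6, 2.6), sd = 0.3)
  rec <- simulate_discrimination_dataset(truth, population_spec(40, 20),
                                         seed = 406, sd_individual = 0.1)
  fit <- fit_discrimination_model(rec, isotope = "d15N",
                                  fixed = c("diet", "sex", "age"))
  expect_match(fit$selected_formula, "diet")
  expect_false(grepl("sex|age", fit$selected_formula))
  co <- fit$coefficients
  terr <- co$estimate[co$term == "dietterrestrial"]
  expect_equal(terr, 1.2, tolerance = 2 * co$std.error[
    co$term == "dietterrestrial"])
  expect_equal(fit$sigma, 0.3, tolerance = 0.1)
})

test_that("a known blood-cells-vs-plasma offset is recovered as a tissue contrast", {
  truth <- tibble::tibble(tissue = c("blood_cells", "plasma"),
                          isotope = "d15N", diet = "mix",
                          sex = NA_character_, age = NA_character_,
                          mean = c(1.8, 3.3), sd = 0.3)
  rec <- simulate_discrimination_dataset(truth, population_spec(40, 40),
                                         seed = 407, sd_individual = 0.15)
  fit <- fit_discrimination_model(rec, isotope = "d15N",
                                  fixed = c("tissue", "sex", "age"))
  co <- fit$coefficients
  pl <- co$estimate[co$term == "tissueplasma"]
  expect_equal(pl, 1.5, tolerance = 0.2)
})

test_that("null data select the intercept-only model most of the time", {
  hits <- vapply(1:60, function(r) {
    truth <- tibble::tibble(tissue = c("plasma", "blood_cells"),
                            isotope = "d15N",
                            diet = "mix", sex = NA_character_,
                            age = NA_character_, mean = 2, sd = 0.3)
    rec <- simulate_discrimination_dataset(truth, population_spec(40, 20),
                                           seed = 20000 + r,
                                           sd_individual = 0)
    fit <- fit_discrimination_model(rec, isotope = "d15N",
                                    fixed = c("sex", "age"),
                                    interactions = FALSE)
    fit$selected_formula == "1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the Welch two-diet comparison matches its design", {
  truth <- default_discrimination_truth()
  rec <- simulate_discrimination_dataset(truth, population_spec(40, 20),
                                         seed = 408, sd_individual = 0.05)
  cmp <- compare_diets_two_sample(rec, "liver", "d15N")
  # generating cell means 1.97 (marine) vs 2.68 (terrestrial)
  expect_equal(cmp$estimate, -0.71, tolerance = 0.45)
  expect_true(cmp$conf.high < 0)

  # identical groups: zero difference
  same <- tibble::tibble(tissue = "liver", isotope = "d15N",
                         diet = rep(c("marine", "terrestrial"), each = 4),
                         discrimination = rep(c(1, 2, 3, 4), 2))
  cmp0 <- compare_diets_two_sample(same, "liver", "d15N")
  expect_equal(cmp0$estimate, 0)
  expect_equal(cmp0$statistic, 0)

  # Welch equals pooled t when variances and sizes match
  tt_pooled <- t.test(c(1, 2, 3, 4), c(2, 3, 4, 5), var.equal = TRUE)
  balanced <- tibble::tibble(tissue = "liver", isotope = "d15N",
                             diet = rep(c("marine", "terrestrial"),
                                        each = 4),
                             discrimination = c(1, 2, 3, 4, 2, 3, 4, 5))
  cmpb <- compare_diets_two_sample(balanced, "liver", "d15N")
  expect_equal(cmpb$statistic, unname(tt_pooled$statistic))
  expect_equal(cmpb$df, unname(tt_pooled$parameter))

  expect_error(compare_diets_two_sample(same[c(1, 5:8), ], "liver",
                                        "d15N"), ">= 2 records")
})
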