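# Closed-form model functions: predictions, half-lives, clock inversion.

test_that("one-compartment predictions hit the anchor points", {
  p <- oc_ref()
  expect_equal(predict_one_compartment(p, 0), 8)
  expect_equal(predict_one_compartment(p, 9), 12, tolerance = 1e-5)
  expect_equal(predict_one_compartment(p, 18), 14, tolerance = 1e-5)
  flat <- one_compartment_params(5, 5, -1)
  expect_equal(predict_one_compartment(flat, 37), 5)
  expect_error(predict_one_compartment(p, -1), "non-negative")
  expect_error(one_compartment_params(Inf, 8, 0), "finite")
})

test_that("one-compartment half-life follows log(2)/exp(phi3)", {
  expect_equal(half_life_one_compartment(0), log(2))
  expect_equal(half_life_one_compartment(log(log(2))), 1)
  expect_equal(half_life_one_compartment(-2.56374), 9, tolerance = 1e-4)
  # strictly decreasing
  phis <- seq(-4, 1, by = 0.25)
  expect_true(all(diff(half_life_one_compartment(phis)) < 0))
  expect_equal(phi3_from_half_life(half_life_one_compartment(-1.3)), -1.3)
})

test_that("midpoint identity holds for arbitrary parameter triples", {
  set.seed(71)
  for (i in 1:25) {
    p <- one_compartment_params(rnorm(1, 0, 10), rnorm(1, 0, 10),
                                rnorm(1, -2, 1.5))
    if (p$phi1 == p$phi2) next
    hl <- half_life_one_compartment(p$phi3)
    expect_equal(predict_one_compartment(p, hl), (p$phi1 + p$phi2) / 2,
                 tolerance = 1e-12)
  }
})

test_that("two-compartment model evaluates correctly and nests the one-pool model", {
  p <- two_compartment_params(16, 8, p = 0.5, k1 = 0.2, k2 = 0.05)
  expect_equal(predict_two_compartment(p, 0), 8)
  expect_equal(predict_two_compartment(p, 10),
               16 - 8 * (0.5 * exp(-2) + 0.5 * exp(-0.5)),
               tolerance = 1e-12)
  # frozen independent evaluation of the same point
  expect_equal(predict_two_compartment(p, 10), 13.0325362, tolerance = 1e-6)

  one <- two_compartment_params(16, 8, p = 1, k1 = exp(-2.56374), k2 = 0.01)
  expect_equal(predict_two_compartment(one, 9), 12, tolerance = 1e-4)
  oc <- one_compartment_params(16, 8, -2.56374)
  ts <- seq(0, 200, by = 0.5)
  expect_lt(max(abs(predict_two_compartment(one, ts) -
                      predict_one_compartment(oc, ts))), 1e-12)

  expect_error(two_compartment_params(16, 8, p = 1.4, k1 = 1, k2 = 0.5),
               "\\[0, 1\\]")
  expect_error(two_compartment_params(16, 8, p = 0.5, k1 = -1, k2 = 0.5),
               "positive")
  # identifiability convention: swapped rates are canonicalised
  sw <- two_compartment_params(16, 8, p = 0.3, k1 = 0.05, k2 = 0.2)
  expect_true(sw$k1 >= sw$k2)
  expect_equal(predict_two_compartment(sw, 7),
               predict_two_compartment(
                 two_compartment_params(16, 8, 0.7, 0.2, 0.05), 7))
})

test_that("two-compartment half-life matches a bisection oracle", {
  expect_equal(half_life_two_compartment(
    two_compartment_params(16, 8, 1, log(2) / 9, 0.001)), 9)
  expect_equal(half_life_two_compartment(
    two_compartment_params(16, 8, 0, 1, log(2) / 40)), 40)

  p <- two_compartment_params(16, 8, p = 0.5, k1 = 0.2, k2 = 0.05)
  # independent oracle: plain interval bisection
  g <- function(t) 0.5 * exp(-0.2 * t) + 0.5 * exp(-0.05 * t) - 0.5
  lo <- 0; hi <- 100
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(half_life_two_compartment(p), (lo + hi) / 2,
               tolerance = 1e-8)
  expect_error(half_life_two_compartment(
    two_compartment_params(5, 5, 0.5, 0.2, 0.05)), "undefined")
})

test_that("isotopic clock inverts the incorporation curve", {
  p <- oc_ref()
  expect_equal(time_since_diet_shift(8, p), 0)
  expect_equal(time_since_diet_shift(12, p), 9, tolerance = 1e-5)
  # round-trip identity across the full usable range
  for (t in c(0, 0.5, 3, 9, 27, 90, 200)) {
    expect_equal(time_since_diet_shift(predict_one_compartment(p, t), p), t,
                 tolerance = 1e-9)
  }
  expect_error(time_since_diet_shift(16, p), "asymptote")
  expect_error(time_since_diet_shift(7.5, p), "outside")
  expect_error(time_since_diet_shift(16.5, p), "outside")
})
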