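test_that("denatured fraction interpolates between the baselines with clipping", {
  expect_equal(as.numeric(fraction_denatured(1.9, 1.9, 0.9)), 0)
  expect_equal(as.numeric(fraction_denatured(0.9, 1.9, 0.9)), 1)
  expect_equal(as.numeric(fraction_denatured(1.4, 1.9, 0.9)), 0.5)
  fd <- fraction_denatured(c(2.0, 0.8), 1.9, 0.9)
  expect_equal(as.numeric(fd), c(0, 1))
  expect_equal(attr(fd, "clipped"), c(TRUE, TRUE))
  expect_error(fraction_denatured(1, 1.5, 1.5), class = "flimaggr_invalid_parameter")
})

test_that("the free-energy transform matches its closed form and window rules", {
  expect_equal(dg_from_fraction(0.5), 0)
  # fD = 0.03305 at 298.15 K corresponds to 2.00 kcal/mol
  expect_equal(dg_from_fraction(0.03305), 2.0, tolerance = 1e-3)
  expect_equal(dg_from_fraction(0.2), -dg_from_fraction(0.8))
  # outside the usable window: excluded as NA, not an exception
  expect_true(is.na(dg_from_fraction(0.01)))
  expect_true(is.na(dg_from_fraction(0.995)))
})

test_that("the unfolding equilibrium constant behaves as exp(-dG/RT)", {
  expect_equal(k_unfolding(0), 1)
  expect_equal(k_unfolding(2.0), exp(-2 / (1.9872e-3 * 298.15)))
  expect_equal(k_unfolding(2.0), 0.0342, tolerance = 1e-3)
  dgs <- c(0, 1, 2, 4, 5.6)
  expect_true(all(diff(k_unfolding(dgs)) < 0))
})

test_that("noiseless denaturation curves round-trip exactly through the stability fit", {
  for (dg in c(2.0, 5.6)) {
    for (m in c(0.8, 1.5)) {
      cv <- simulate_denaturation_curve(dg, m, urea_grid = seq(0, 10, 0.5))
      fit <- stability_fit(cv, 1.9, 0.9)
      expect_equal(fit$dg_water, dg, tolerance = 1e-6)
      expect_equal(fit$m_value, m, tolerance = 1e-6)
      expect_equal(fit$cm, dg / m, tolerance = 1e-6)
      expect_equal(fit$k_unf, k_unfolding(dg), tolerance = 1e-6)
      # dG at the midpoint is zero by construction
      expect_equal(fit$dg_water - fit$m_value * fit$cm, 0, tolerance = 1e-9)
    }
  }
})

test_that("an exact free-energy line is recovered exactly", {
  urea <- seq(2, 6, by = 1)
  rt <- 1.9872e-3 * 298.15
  fd <- 1 / (1 + exp((5.6 - 1.2 * urea) / rt))
  ratio <- 1.9 + fd * (0.9 - 1.9)
  fit <- stability_fit(data.frame(urea_M = urea, ratio = ratio), 1.9, 0.9)
  expect_equal(fit$dg_water, 5.6, tolerance = 1e-9)
  expect_equal(fit$m_value, 1.2, tolerance = 1e-9)
})

test_that("baseline auto-estimation from the curve ends reproduces supplied baselines", {
  # steep transition far from both ends, so the end points sit on the baselines
  cv <- simulate_denaturation_curve(5.6, 1.2, urea_grid = seq(0, 10, 0.5))
  fit_auto <- stability_fit(cv)
  fit_given <- stability_fit(cv, 1.9, 0.9)
  expect_equal(fit_auto$dg_water, fit_given$dg_water, tolerance = 0.02)
})

test_that("too few usable points raise an insufficient-data error", {
  cv <- simulate_denaturation_curve(5.6, 1.0, urea_grid = c(0, 0.5, 1))
  expect_error(stability_fit(cv, 1.9, 0.9), class = "flimaggr_insufficient_data")
})

test_that("metastability regression diagnoses colinear, degenerate and noisy designs", {
  k <- c(0.001, 0.01, 0.03, 0.05)
  col <- metastability_regression(k, 0.001 + 0.5 * k)
  expect_equal(col$r_squared, 1, tolerance = 1e-12)
  expect_equal(col$slope, 0.5, tolerance = 1e-9)
  expect_warning(deg <- metastability_regression(rep(0.02, 4), c(1, 2, 3, 4) / 100),
                 regexp = "undefined")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$slope))
  expect_error(metastability_regression(c(1, 2), c(1, 2)),
               class = "flimaggr_insufficient_data")
  # a positive linear law + noise: slope recovered within 2 se
  set.seed(77)
  truth_slope <- 0.6
  ok <- vapply(1:20, function(i) {
    y <- 0.002 + truth_slope * k + rnorm(4, 0, 0.002)
    f <- metastability_regression(k, y)
    abs(f$slope - truth_slope) < 2 * f$slope_se + 1e-12
  }, logical(1))
  expect_gt(mean(ok), 0.8)
})
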