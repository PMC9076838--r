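test_that("the diffusion model has the right limits and mixture behaviour", {
  # amplitude limit
  expect_equal(fcs_model(1e-12, 5, list(c(3e-3, 1))), 1 / 5, tolerance = 1e-6)
  # 2-D limit: at tau = tau_D with kappa -> infinity, G-1 = (1/N)/2
  expect_equal(fcs_model(3e-3, 5, list(c(3e-3, 1)), kappa = 1e9),
               (1 / 5) / 2, tolerance = 1e-6)
  # a degenerate mixture with fraction (1, 0) equals the single species
  lag <- 10^seq(-6, 1, length.out = 50)
  expect_equal(fcs_model(lag, 5, list(c(3e-3, 1), c(3e-2, 0))),
               fcs_model(lag, 5, list(c(3e-3, 1))))
  # slow component dominates beyond the crossover
  g1 <- fcs_model(lag, 5, list(c(1e-3, 1)))
  g2 <- fcs_model(lag, 5, list(c(1e-3, 0.5), c(1e-2, 0.5)))
  expect_true(all(g2[lag >= 1e-3] >= g1[lag >= 1e-3]))
  expect_error(fcs_model(lag, 5, list(c(1e-3, 0.6), c(1e-2, 0.6))),
               class = "flimaggr_invalid_parameter")
})

test_that("focal-volume calibration and Stokes-Einstein conversions are exact inverses", {
  w0 <- calibrate_focal_volume(36.8e-6, 425)
  expect_equal(w0, sqrt(4 * 425 * 36.8e-6))  # about 0.25 um
  expect_equal(w0, 0.25, tolerance = 2e-3)
  expect_equal(calibrate_focal_volume(2 * 36.8e-6) / w0, sqrt(2))
  # algebraic round trip
  expect_equal(diffusion_from_tau(36.8e-6, w0), 425, tolerance = 1e-12)
  # hand-derived values at 298.15 K, 0.00089 Pa s
  expect_equal(stokes_einstein_radius(425), 0.577, tolerance = 1e-3)
  expect_equal(stokes_einstein_radius(5.11), 48.0, tolerance = 1e-3)
  expect_equal(stokes_einstein_diffusion(48), 5.11, tolerance = 1e-3)
  # Rh * D is a conserved quantity at fixed conditions: kB T / (6 pi eta)
  d <- c(1, 5.11, 425)
  prod <- stokes_einstein_radius(d) * d                  # nm um^2/s
  expect_equal(max(prod) - min(prod), 0, tolerance = 1e-9)
  expect_equal(prod[1] * 1e-9 * 1e-12,
               1.380649e-23 * 298.15 / (6 * pi * 0.00089), tolerance = 1e-12)
})

test_that("noiseless curves round-trip through the fit to 1e-6 relative", {
  cv <- simulate_fcs_curve(list(c(48, 1)), n_mean = 5, w0 = 0.25)
  truth <- attr(cv, "truth")
  fit <- fit_fcs(cv, w0 = 0.25)
  expect_equal(fit$n_mean, 5, tolerance = 1e-6)
  expect_equal(fit$species$tau_d_s, truth$tau_d, tolerance = 1e-6)
  expect_equal(fit$species$rh_nm, 48, tolerance = 1e-6)
  # two species, noiseless
  cv2 <- simulate_fcs_curve(list(c(2.9, 0.6), c(48, 0.4)), n_mean = 3,
                            w0 = 0.25)
  truth2 <- attr(cv2, "truth")
  fit2 <- fit_fcs(cv2, n_species = 2, w0 = 0.25)
  expect_equal(fit2$species$tau_d_s, sort(truth2$tau_d), tolerance = 1e-5)
  expect_equal(fit2$species$fraction, truth2$fraction, tolerance = 1e-5)
  expect_equal(fit2$species$rh_nm, c(2.9, 48), tolerance = 1e-4)
})

test_that("diffusion-time errors stay below 2 percent at 1 percent noise", {
  errs <- vapply(1:50, function(s) {
    cv <- simulate_fcs_curve(list(c(48, 1)), n_mean = 5, w0 = 0.25,
                             noise_sd_rel = 0.01, seed = 700 + s)
    fit <- fit_fcs(cv)
    abs(fit$species$tau_d_s / attr(cv, "truth")$tau_d - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("a two-species fit of a one-species curve is flagged degenerate or collapses a fraction", {
  cv <- simulate_fcs_curve(list(c(48, 1)), n_mean = 5, w0 = 0.25)
  fit2 <- withCallingHandlers(
    fit_fcs(cv, n_species = 2,
            init = list(tau_d = c(2.8e-3, 3.4e-3), fraction = c(0.5, 0.5))),
    warning = function(w) invokeRestart("muffleWarning"))
  tau_ratio <- fit2$species$tau_d_s[2] / fit2$species$tau_d_s[1]
  expect_true(fit2$degenerate || max(fit2$species$fraction) > 0.999 ||
                abs(log(tau_ratio)) < 0.05)
})

test_that("the two-species fit never has a larger residual than the one-species fit", {
  for (s in 1:5) {
    cv <- simulate_fcs_curve(list(c(2.9, 0.5), c(48, 0.5)), n_mean = 4,
                             w0 = 0.25, noise_sd_rel = 0.01, seed = 800 + s)
    r1 <- fit_fcs(cv, n_species = 1)$residual_norm
    r2 <- suppressWarnings(fit_fcs(cv, n_species = 2)$residual_norm)
    expect_lte(r2, r1 + 1e-9)
  }
})

test_that("curve validation refuses short, unsorted or non-positive input", {
  expect_error(fit_fcs(data.frame(lag_s = 1:5 * 1e-3, g_minus_1 = 1)),
               class = "flimaggr_invalid_input")
  cv <- simulate_fcs_curve(list(c(48, 1)), n_mean = 5)
  cv$g_minus_1 <- -abs(cv$g_minus_1)
  expect_error(fit_fcs(cv), class = "flimaggr_invalid_input")
})

test_that("DLS fits recover the decay rate and Dh = 2 Rh", {
  q <- dls_q(173, 633, 1.33)
  d_true <- 5.11e-12            # m^2/s, a 48 nm particle
  gamma <- d_true * q^2
  delay <- 10^seq(-6, -1, length.out = 60)
  g2 <- 0.9 * exp(-2 * gamma * delay)
  fit <- dls_fit(delay, g2, q)
  expect_equal(fit$gamma_s, gamma, tolerance = 1e-6)
  expect_equal(fit$d_um2s, 5.11, tolerance = 1e-6)
  expect_equal(fit$dh_nm, 2 * fit$rh_nm)
  expect_equal(fit$dh_nm, 2 * stokes_einstein_radius(5.11), tolerance = 1e-6)
  # 2 percent noise, 20 seeds: median error under 5 percent
  errs <- vapply(1:20, function(s) {
    g2n <- with_seed_test(900 + s, g2 * (1 + rnorm(length(g2), 0, 0.02)))
    abs(dls_fit(delay, g2n, q)$d_um2s / 5.11 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  # non-decaying input
  expect_error(dls_fit(delay, rep(0.5, 60), q), class = "flimaggr_fit_failure")
})
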