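test_that("IRF centroid follows the average-channel definition and is shift-equivariant", {
  expect_equal(irf_centroid(delta_irf(0)), 0)
  irf <- tcspc_histogram(c(0, 0, 5, 0, 5), bin_width = 0.5, rep_period = 50)
  expect_equal(irf_centroid(irf), 1.5)  # mean of indices 2 and 4, times 0.5
  # short lifetime keeps the wrapped tail mass negligible
  base <- analytic_decay(2, bin_width = 0.5)
  shifted <- analytic_decay(2, bin_width = 0.5, shift_bins = 7)
  expect_equal(irf_centroid(shifted) - irf_centroid(base), 7 * 0.5,
               tolerance = 1e-6)
  empty <- tcspc_histogram(numeric(10), 0.016, 50)
  expect_error(irf_centroid(empty), class = "flimaggr_invalid_input")
})

test_that("mean-arrival lifetime reproduces the truncated-exponential values on noiseless decays", {
  irf0 <- delta_irf(0)
  # native-probe lifetime: correction below 2e-5 ns, so the estimate is
  # 3.3000 within one bin width
  expect_equal(mean_arrival_lifetime(analytic_decay(3.3), irf0), 3.3,
               tolerance = 0.016 / 3.3)
  # long aggregate lifetime: truncation bias is visible (about 7.53, not 7.6)
  est76 <- mean_arrival_lifetime(analytic_decay(7.6), irf0)
  expect_equal(est76, truncated_exp_mean(7.6, 50), tolerance = 0.016 / 7.6)
  expect_lt(est76, 7.56)
  # equal-photon mixture: photon-weighted mean of the single-component values
  mix <- analytic_decay(3.3)
  mix$counts <- mix$counts + analytic_decay(7.6)$counts
  expect_equal(mean_arrival_lifetime(mix, irf0),
               (truncated_exp_mean(3.3, 50) + truncated_exp_mean(7.6, 50)) / 2,
               tolerance = 0.016 / 5.4)
})

test_that("estimator equals the brute-force photon-list mean and the bias law holds", {
  # oracle equivalence on an arbitrary small histogram
  set.seed(5)
  counts <- rpois(200, 3)
  h <- tcspc_histogram(counts, 0.25, 50)
  photons <- rep(seq_along(counts) - 1, counts)
  brute <- mean(photons) * 0.25
  expect_equal(mean_arrival_lifetime(h, delta_irf(0, bin_width = 0.25)),
               brute, tolerance = 1e-9)
  # bias law over the probe-relevant lifetimes
  for (tau in c(1, 3.3, 5, 7.6)) {
    est <- mean_arrival_lifetime(analytic_decay(tau), delta_irf(0))
    expect_lt(abs(est - truncated_exp_mean(tau, 50)), 0.016 / 2 + 1e-9)
  }
  # optional wrap-aware correction inverts the bias
  est_corr <- mean_arrival_lifetime(analytic_decay(7.6), delta_irf(0),
                                    correct_truncation = TRUE)
  expect_equal(est_corr, 7.6, tolerance = 0.016 / 7.6)
})

test_that("estimator is linear in photon-fraction mixtures and monotone in lifetime", {
  irf0 <- delta_irf(0)
  singles <- vapply(c(2.5, 6.0), function(tau)
    mean_arrival_lifetime(analytic_decay(tau), irf0), numeric(1))
  for (f in c(0.2, 0.5, 0.8)) {
    mix <- analytic_decay(2.5)
    mix$counts <- f * mix$counts + (1 - f) * analytic_decay(6.0)$counts
    expect_equal(mean_arrival_lifetime(mix, irf0),
                 f * singles[1] + (1 - f) * singles[2], tolerance = 1e-7)
  }
  taus <- c(0.5, 1, 2, 3.3, 5, 7.6, 12)
  ests <- vapply(taus, function(tau)
    mean_arrival_lifetime(analytic_decay(tau), irf0), numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("binning mismatches and empty decays are refused", {
  expect_error(
    mean_arrival_lifetime(analytic_decay(3.3, bin_width = 0.016),
                          delta_irf(0, bin_width = 0.025)),
    class = "flimaggr_incompatible_input")
  empty <- tcspc_histogram(numeric(3125), 0.016, 50)
  expect_error(mean_arrival_lifetime(empty, delta_irf(0)),
               class = "flimaggr_invalid_input")
})

test_that("lifetime images are unimodal at the native lifetime and scale-invariant", {
  sc <- quick_scene(seed = 21, puncta_per_cell = 0, photons = 500)
  irf <- quick_irf()
  img <- lifetime_image(sc$stack, irf, min_photons = 100)
  v <- img$tau[!is.na(img$tau)]
  expect_gt(length(v), 100)
  dens <- stats::density(v)
  expect_lt(abs(dens$x[which.max(dens$y)] - 3.3), 0.05)
  # doubling every pixel's counts leaves the lifetimes unchanged
  stack2 <- flim_stack(sc$stack$counts * 2, sc$stack$bin_width,
                       sc$stack$rep_period, sc$stack$pixel_size)
  img2 <- lifetime_image(stack2, irf, min_photons = 100)
  expect_equal(img2$tau[!is.na(img2$tau)], img$tau[!is.na(img$tau)],
               tolerance = 1e-12)
  # all pixels below the photon threshold: all-invalid image, no error
  img3 <- lifetime_image(sc$stack, irf, min_photons = 1e7)
  expect_true(all(is.na(img3$tau)))
})

test_that("per-region lifetime statistics normalise and average correctly", {
  img <- structure(
    list(tau = matrix(c(3.3, 3.3, 6.0, 6.0, NA, 3.3), 2, 3),
         photons = matrix(500, 2, 3), min_photons = 100,
         rep_period = 50, pixel_size = 0.1),
    class = "lifetime_image")
  mask <- matrix(c(1, 1, 1, 1, 2, 0), 2, 3)
  st <- pixel_lifetime_stats(img, mask, bin_edges = seq(0, 10, 0.5))
  expect_equal(st$means$mean_ns[st$means$label == 1], mean(c(3.3, 3.3, 6, 6)))
  # region 2 has only an invalid pixel: flagged, empty histogram, NA mean
  expect_true(st$means$flagged[st$means$label == 2])
  expect_true(is.na(st$means$mean_ns[st$means$label == 2]))
  h1 <- st$hist[st$hist$label == 1, ]
  expect_equal(sum(h1$frequency), 1)
  expect_equal(sum(h1$frequency[h1$bin_lo <= 3.3 & h1$bin_hi > 3.3]), 0.5)
  expect_equal(sum(st$hist$frequency[st$hist$label == 2]), 0)
})
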