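# Analytic (noiseless) binned truncated-exponential decay with an ideal
# delta IRF shifted by `shift_bins`. Probabilities are scaled to a large
# integer total so the container's non-negativity contract holds while the
# rounding error stays below 1e-9 of the centroid.
analytic_decay <- function(tau, rep_period = 50, bin_width = 0.016,
                           shift_bins = 0, total = 1e12) {
  n <- as.integer(round(rep_period / bin_width))
  edges <- (0:n) * bin_width
  p <- diff(stats::pexp(edges, rate = 1 / tau)) /
    stats::pexp(rep_period, rate = 1 / tau)
  if (shift_bins > 0)
    p <- c(utils::tail(p, -(n - shift_bins)), utils::head(p, n - shift_bins))
  tcspc_histogram(round(p * total), bin_width, rep_period)
}

# Delta IRF: all counts in one bin (index from 0).
delta_irf <- function(bin = 0, rep_period = 50, bin_width = 0.016,
                      counts = 1e6) {
  n <- as.integer(round(rep_period / bin_width))
  x <- numeric(n)
  x[bin + 1] <- counts
  tcspc_histogram(x, bin_width, rep_period)
}

# Centroid of an analytic histogram by brute-force photon expansion is
# impractical at 1e12 photons; the small-count brute force used in the
# oracle-equivalence test lives in the test file itself.

# CDF of the exGaussian arrival-time model (Gaussian IRF convolved with an
# exponential decay): the independent distributional oracle for the
# simulator's chi-square goodness-of-fit test.
exgauss_cdf <- function(t, center, sigma, tau) {
  z <- (t - center) / sigma
  pnorm(z) - exp(sigma^2 / (2 * tau^2) - (t - center) / tau) *
    pnorm(z - sigma / tau)
}

# Bin probabilities of the exGaussian arrival time wrapped modulo the
# repetition period (photons later than the window fold onto early bins,
# the Gaussian's negative tail onto late bins).
exgauss_wrapped_probs <- function(edges, center, sigma, tau, rep_period,
                                  wraps = -1:6) {
  p <- 0
  for (k in wraps)
    p <- p + diff(exgauss_cdf(edges + k * rep_period, center, sigma, tau))
  p / sum(p)
}

# Pool histogram bins (observed counts + model probabilities) so every
# pooled class has expected count >= min_expected, as chi-square requires.
pool_bins <- function(observed, prob, n_total, min_expected = 5) {
  obs_p <- integer(0); pr_p <- numeric(0)
  acc_o <- 0; acc_p <- 0
  for (i in seq_along(observed)) {
    acc_o <- acc_o + observed[i]; acc_p <- acc_p + prob[i]
    if (acc_p * n_total >= min_expected) {
      obs_p <- c(obs_p, acc_o); pr_p <- c(pr_p, acc_p)
      acc_o <- 0; acc_p <- 0
    }
  }
  if (acc_p > 0) {  # fold the remainder into the last class
    obs_p[length(obs_p)] <- obs_p[length(obs_p)] + acc_o
    pr_p[length(pr_p)] <- pr_p[length(pr_p)] + acc_p
  }
  list(observed = obs_p, prob = pr_p)
}

# Small, fast synthetic scene used across detector tests.
quick_scene <- function(seed, puncta_per_cell = 2, puncta_tau = c(6, 6),
                        n_cells = 3, photons = 300) {
  spec <- scene_spec(image_size = c(64, 64), n_cells = n_cells,
                     cell_axes = c(9, 13),
                     puncta_per_cell = puncta_per_cell,
                     puncta_tau_range = puncta_tau,
                     puncta_radius_range = c(2.5, 4),
                     photons_per_pixel = photons, seed = seed)
  simulate_flim_scene(spec, rep_period = 50, bin_width = 0.5)
}

quick_irf <- function(seed = 99, bin_width = 0.5) {
  simulate_irf(2e5, rep_period = 50, bin_width = bin_width, seed = seed)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}

withr_tempdir <- function() {
  d <- tempfile("flimaggr-test-")
  dir.create(d)
  d
}
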