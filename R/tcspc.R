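#' TCSPC decay histogram
#'
#' Container for a time-correlated single-photon counting (TCSPC) histogram:
#' photon counts per time bin within one laser repetition period.
#'
#' @param counts Non-negative photon counts, one per TCSPC bin (bin 0 first).
#' @param bin_width Bin width ("time resolution") in ns.
#' @param rep_period Laser repetition period in ns (50 ns at 20 MHz).
#' @return An object of class `tcspc_histogram` with fields `counts`,
#'   `bin_width`, `rep_period`, `n_bins`.
#' @examples
#' h <- tcspc_histogram(c(0, 10, 5, 1), bin_width = 0.5, rep_period = 2)
#' sum(h$counts)
#' @export
tcspc_histogram <- function(counts, bin_width, rep_period) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(!is.finite(counts)) || any(counts < 0))
    stop_invalid("`counts` must be finite and non-negative")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop_invalid("`bin_width` must be positive")
  if (!is.numeric(rep_period) || rep_period <= 0)
    stop_invalid("`rep_period` must be positive")
  if (length(counts) * bin_width > rep_period + bin_width + 1e-9)
    stop_invalid("histogram spans more than one repetition period")
  structure(
    list(counts = counts, bin_width = bin_width, rep_period = rep_period,
         n_bins = length(counts)),
    class = "tcspc_histogram"
  )
}

#' @export
print.tcspc_histogram <- function(x, ...) {
  cat(sprintf("TCSPC histogram: %d bins x %.4g ns (window %.4g ns), %s photons\n",
              x$n_bins, x$bin_width, x$rep_period,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' FLIM photon-count cube
#'
#' A TCSPC histogram per pixel: a rows x cols x n_bins array of photon counts
#' plus the acquisition metadata needed to interpret it.
#'
#' @param counts Integer-valued array of dimension rows x cols x n_bins.
#' @param bin_width TCSPC bin width in ns.
#' @param rep_period Repetition period in ns.
#' @param pixel_size Pixel size in micrometres.
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(counts, bin_width, rep_period, pixel_size) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop_invalid("`counts` must be a rows x cols x n_bins array")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop_invalid("stack counts must be finite and non-negative")
  if (bin_width <= 0 || rep_period <= 0 || pixel_size <= 0)
    stop_invalid("stack metadata must be positive")
  structure(
    list(counts = counts, bin_width = bin_width, rep_period = rep_period,
         pixel_size = pixel_size, n_bins = dim(counts)[3]),
    class = "flim_stack"
  )
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("FLIM stack: %d x %d px, %d bins x %.4g ns, %.3g um/px, %s photons\n",
              d[1], d[2], d[3], x$bin_width, x$pixel_size,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

# Bin wrapped arrival times (ns) into a tcspc_histogram.
bin_arrivals <- function(t, rep_period, bin_width) {
  n_bins <- as.integer(round(rep_period / bin_width))
  idx <- floor((t %% rep_period) / bin_width) + 1L
  idx[idx > n_bins] <- n_bins  # guard against t == rep_period after rounding
  tcspc_histogram(tabulate(idx, nbins = n_bins), bin_width, rep_period)
}

check_binning <- function(rep_period, bin_width) {
  if (bin_width >= rep_period)
    stop_invalid("`bin_width` must be smaller than `rep_period`")
  k <- rep_period / bin_width
  if (abs(k - round(k)) > 1e-6)
    stop_invalid("`rep_period` must be an integer multiple of `bin_width`")
}

#' Simulate a TCSPC decay histogram
#'
#' Draws photon arrival times as an instrument-response (Gaussian) draw plus a
#' single-exponential decay draw, wraps them into the repetition period (photons
#' emitted after the next pulse appear at early channels, as in a real TCSPC
#' experiment), and bins them.
#'
#' @param components List of `c(lifetime_ns, fraction)` pairs (or a 2-column
#'   matrix); photon fractions must sum to 1.
#' @param n_photons Total number of photons; the returned histogram contains
#'   exactly this many counts.
#' @param rep_period Repetition period in ns. Default 50 (20 MHz).
#' @param bin_width Bin width in ns. Default 0.016 (3125 bins over 50 ns).
#' @param irf Instrument response, `c(center_ns, fwhm_ns)`; a Gaussian. Use
#'   `fwhm = 0` for an ideal delta IRF.
#' @param seed Optional integer seed; the same seed gives a bit-identical
#'   histogram. The caller's RNG state is restored.
#' @return A [tcspc_histogram()].
#' @examples
#' h <- simulate_tcspc(list(c(3.3, 1)), n_photons = 1e4, seed = 1)
#' sum(h$counts)
#' @export
simulate_tcspc <- function(components, n_photons, rep_period = 50,
                           bin_width = 0.016, irf = c(2, 0.2), seed = NULL) {
  comp <- as_components(components)
  if (!is.numeric(n_photons) || length(n_photons) != 1L || n_photons < 1)
    stop_invalid("`n_photons` must be a positive count")
  n_photons <- as.integer(round(n_photons))
  check_binning(rep_period, bin_width)
  irf <- check_irf(irf)
  with_seed(seed, {
    k <- sample.int(nrow(comp), n_photons, replace = TRUE, prob = comp[, 2])
    tau <- comp[k, 1]
    t0 <- if (irf[2] > 0) rnorm(n_photons, irf[1], fwhm_to_sd(irf[2])) else irf[1]
    bin_arrivals(t0 + rexp(n_photons, rate = 1 / tau), rep_period, bin_width)
  })
}

#' Simulate an IRF histogram
#'
#' Scattered-light record of the instrument response: Gaussian arrival times
#' with no fluorescence decay, binned like a decay histogram.
#'
#' @inheritParams simulate_tcspc
#' @param center Gaussian IRF centre in ns.
#' @param fwhm Gaussian IRF full width at half maximum in ns; 0 gives a delta.
#' @return A [tcspc_histogram()].
#' @export
simulate_irf <- function(n_photons, center = 2, fwhm = 0.2, rep_period = 50,
                         bin_width = 0.016, seed = NULL) {
  if (!is.numeric(n_photons) || n_photons < 1)
    stop_invalid("`n_photons` must be a positive count")
  n_photons <- as.integer(round(n_photons))
  check_binning(rep_period, bin_width)
  irf <- check_irf(c(center, fwhm))
  with_seed(seed, {
    t0 <- if (irf[2] > 0) rnorm(n_photons, irf[1], fwhm_to_sd(irf[2]))
          else rep(irf[1], n_photons)
    bin_arrivals(t0, rep_period, bin_width)
  })
}

#' Mean of a single-exponential decay truncated to one repetition window
#'
#' Closed form for the mean arrival time of an exponential decay with lifetime
#' `tau` observed only on `[0, T)`:
#' `tau - T * exp(-T/tau) / (1 - exp(-T/tau))`. This is the value the
#' mean-arrival estimator converges to; the shortfall below `tau` is the
#' finite-window truncation bias.
#'
#' @param tau Lifetime in ns.
#' @param rep_period Window length T in ns.
#' @return Truncated mean in ns.
#' @examples
#' truncated_exp_mean(7.6, 50)  # about 7.53 ns
#' @export
truncated_exp_mean <- function(tau, rep_period) {
  q <- exp(-rep_period / tau)
  tau - rep_period * q / (1 - q)
}

fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

check_irf <- function(irf) {
  irf <- as.numeric(unlist(irf))
  if (length(irf) != 2L || any(!is.finite(irf)) || irf[2] < 0)
    stop_invalid("`irf` must be c(center_ns, fwhm_ns) with fwhm >= 0")
  irf
}

as_components <- function(components) {
  if (is.list(components)) components <- do.call(rbind, components)
  comp <- matrix(as.numeric(components), ncol = 2)
  if (any(!is.finite(comp))) stop_invalid("components must be finite")
  if (any(comp[, 1] <= 0)) stop_invalid("component lifetimes must be positive")
  if (any(comp[, 2] < 0) || abs(sum(comp[, 2]) - 1) > 1e-9)
    stop_invalid("component photon fractions must be non-negative and sum to 1")
  comp
}
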