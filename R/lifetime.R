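#' IRF centroid
#'
#' Average TCSPC channel of the instrument response, expressed in ns. Bin
#' indices count from 0 (left edge), so a histogram with all counts in bin 0
#' has centroid 0.
#'
#' @param irf A [tcspc_histogram()] with at least one photon.
#' @return Centroid in ns.
#' @examples
#' irf <- tcspc_histogram(c(0, 0, 5, 0, 5), bin_width = 0.5, rep_period = 50)
#' irf_centroid(irf)  # 1.5 ns
#' @export
irf_centroid <- function(irf) {
  stopifnot(inherits(irf, "tcspc_histogram"))
  total <- sum(irf$counts)
  if (total <= 0)
    stop(errorCondition("IRF histogram is empty",
                        class = c("flimaggr_invalid_input", "error", "condition")))
  sum(irf$counts * (seq_along(irf$counts) - 1)) / total * irf$bin_width
}

#' Mean-arrival (FastFLIM) lifetime estimate
#'
#' The distance between the average TCSPC channel of the decay and the average
#' TCSPC channel of the IRF, multiplied by the time resolution. Because the
#' decay is observed only within one repetition window, the estimate falls
#' short of the true lifetime by the truncation bias
#' `T*exp(-T/tau)/(1 - exp(-T/tau))` (see [truncated_exp_mean()]); this bias is
#' reported, not corrected, unless `correct_truncation = TRUE`.
#'
#' @param decay,irf [tcspc_histogram()] objects sharing bin width and bin
#'   count; `decay` must contain at least one photon.
#' @param correct_truncation If `TRUE`, invert the truncation bias law to
#'   return an unbiased lifetime (assumes a mono-exponential decay). Off by
#'   default, matching the plain mean-arrival convention.
#' @return Lifetime estimate in ns.
#' @export
mean_arrival_lifetime <- function(decay, irf, correct_truncation = FALSE) {
  stopifnot(inherits(decay, "tcspc_histogram"), inherits(irf, "tcspc_histogram"))
  if (abs(decay$bin_width - irf$bin_width) > 1e-9 * decay$bin_width ||
      decay$n_bins != irf$n_bins)
    stop_incompatible("decay and IRF histograms must share bin width and bin count")
  if (sum(decay$counts) <= 0)
    stop(errorCondition("decay histogram has no photons",
                        class = c("flimaggr_invalid_input", "error", "condition")))
  est <- irf_centroid(decay) - irf_centroid(irf)
  if (correct_truncation) est <- invert_truncation(est, decay$rep_period)
  est
}

# Solve truncated_exp_mean(tau, T) = m for tau by monotone bisection.
invert_truncation <- function(m, rep_period) {
  if (!is.finite(m) || m <= 0) return(m)
  if (m >= rep_period / 2) return(Inf)  # truncated mean saturates at T/2
  lo <- m; hi <- rep_period * 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (truncated_exp_mean(mid, rep_period) < m) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-pixel lifetime image from a FLIM stack
#'
#' Applies the mean-arrival estimator to every pixel with at least
#' `min_photons` photons; dimmer pixels are marked invalid (`NA`) rather than
#' reported with an unreliable lifetime.
#'
#' @param stack A [flim_stack()].
#' @param irf A [tcspc_histogram()] compatible with the stack binning.
#' @param min_photons Minimum photon total for a valid pixel. Default 100,
#'   which puts the single-pixel lifetime standard error near tau/10.
#' @param correct_truncation Passed to the estimator; off by default.
#' @return An object of class `lifetime_image` with fields `tau` (ns matrix,
#'   `NA` where invalid), `photons` (count matrix), `min_photons`,
#'   `rep_period`, `pixel_size`.
#' @export
lifetime_image <- function(stack, irf, min_photons = 100,
                           correct_truncation = FALSE) {
  stopifnot(inherits(stack, "flim_stack"), inherits(irf, "tcspc_histogram"))
  d <- dim(stack$counts)
  if (prod(d) == 0)
    stop(errorCondition("empty FLIM stack",
                        class = c("flimaggr_invalid_input", "error", "condition")))
  if (abs(stack$bin_width - irf$bin_width) > 1e-9 * stack$bin_width ||
      d[3] != irf$n_bins)
    stop_incompatible("stack and IRF binning are incompatible")
  n_px <- d[1] * d[2]
  M <- matrix(stack$counts, n_px, d[3])
  tot <- rowSums(M)
  cen <- as.vector(M %*% (seq_len(d[3]) - 1)) / tot * stack$bin_width
  tau <- cen - irf_centroid(irf)
  if (correct_truncation)
    tau <- vapply(tau, invert_truncation, numeric(1), rep_period = stack$rep_period)
  tau[tot < min_photons] <- NA_real_
  tau <- pmin(pmax(tau, 0), stack$rep_period)
  structure(
    list(tau = matrix(tau, d[1], d[2]), photons = matrix(tot, d[1], d[2]),
         min_photons = min_photons, rep_period = stack$rep_period,
         pixel_size = stack$pixel_size),
    class = "lifetime_image"
  )
}

#' @export
print.lifetime_image <- function(x, ...) {
  v <- x$tau[!is.na(x$tau)]
  cat(sprintf("Lifetime image: %d x %d px, %d valid (min %g photons)",
              nrow(x$tau), ncol(x$tau), length(v), x$min_photons))
  if (length(v))
    cat(sprintf("; tau %.2f-%.2f ns (median %.2f)", min(v), max(v), median(v)))
  cat("\n")
  invisible(x)
}

#' Per-region pixel-lifetime histograms and means
#'
#' For each labelled region (label 0 = background, excluded): the normalised
#' frequency distribution of valid pixel lifetimes over `bin_edges`, and the
#' mean lifetime. Regions with no valid pixels are reported with an empty
#' histogram and `NA` mean, flagged rather than dropped.
#'
#' @param img A [lifetime_image()].
#' @param mask Integer label matrix of the same shape (e.g. a cell mask).
#' @param bin_edges Histogram bin edges in ns. Default covers the whole
#'   repetition window in 0.1 ns steps.
#' @return A list of class `lifetime_stats`: `$means` (data frame with
#'   `label`, `n_valid`, `mean_ns`, `flagged`) and `$hist` (long data frame
#'   with `label`, `bin_lo`, `bin_hi`, `frequency`; frequencies sum to 1 per
#'   region with any valid pixel inside the range).
#' @export
pixel_lifetime_stats <- function(img, mask,
                                 bin_edges = seq(0, img$rep_period, by = 0.1)) {
  stopifnot(inherits(img, "lifetime_image"))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(img$tau)))
    stop_incompatible("mask shape does not match the lifetime image")
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE))
    stop_invalid("`bin_edges` must be strictly increasing with >= 2 edges")
  labs <- setdiff(sort(unique(as.vector(mask))), 0)
  n_bins <- length(bin_edges) - 1L
  means <- data.frame(label = labs, n_valid = 0L, mean_ns = NA_real_,
                      flagged = FALSE)
  hist_rows <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    v <- img$tau[mask == labs[i]]
    v <- v[!is.na(v)]
    means$n_valid[i] <- length(v)
    if (length(v)) {
      means$mean_ns[i] <- mean(v)
      idx <- findInterval(v, bin_edges, rightmost.closed = TRUE)
      freq <- tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins) / length(v)
    } else {
      means$flagged[i] <- TRUE
      freq <- rep(0, n_bins)
    }
    hist_rows[[i]] <- data.frame(label = labs[i],
                                 bin_lo = bin_edges[-length(bin_edges)],
                                 bin_hi = bin_edges[-1], frequency = freq)
  }
  structure(list(means = means, hist = do.call(rbind, hist_rows)),
            class = "lifetime_stats")
}
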