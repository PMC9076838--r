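as_turnover_series <- function(series, need_intensity = FALSE) {
  series <- as.data.frame(series)
  t <- series[["time_h"]] %||% series[[1]]
  conf <- series[["confluence_pct"]] %||% series[[2]]
  out <- data.frame(time_h = t, confluence_pct = conf)
  if (need_intensity)
    out$tmr_intensity <- series[["tmr_intensity"]] %||% series[[3]]
  if (any(!is.finite(unlist(out))))
    stop_invalid("series contains non-finite values")
  if (is.unsorted(out$time_h, strictly = TRUE))
    stop_invalid("time points must be strictly increasing")
  out
}

#' Fit exponential growth (doubling time)
#'
#' Least squares of `log2(confluence)` on time; the model is
#' `conf_t = conf_0 * 2^(t/td)`, so the doubling time is the reciprocal
#' slope. A non-growing series (slope <= 0) is returned flagged with
#' `td = Inf` rather than raising an error.
#'
#' @param series Data frame with columns `time_h`, `confluence_pct` (or first
#'   two columns in that order).
#' @return List of class `growth_fit`: `td_h`, `td_se_h`, `slope`,
#'   `negative_growth` flag, `r_squared`.
#' @export
fit_growth <- function(series) {
  s <- as_turnover_series(series)
  if (nrow(s) < 4L) stop_insufficient("need >= 4 time points")
  if (any(s$confluence_pct <= 0))
    stop_invalid("confluence must be positive everywhere")
  fit <- lm(log2(confluence_pct) ~ time_h, data = s)
  sm <- suppressWarnings(summary(fit))  # noiseless input fits exactly
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  negative <- !is.finite(slope) || slope <= 0
  if (negative) warning("series is not growing; doubling time is undefined (Inf)")
  structure(
    list(td_h = if (negative) Inf else 1 / slope,
         td_se_h = if (negative) NA_real_ else se / slope^2,
         slope = slope, negative_growth = negative,
         r_squared = sm$r.squared),
    class = "growth_fit"
  )
}

#' Fit pulse-chase turnover kinetics
#'
#' Normalises the label intensity by confluence (dividing out the dilution of
#' label across daughter cells, since division is typically faster than
#' degradation), then fits a first-order decay by least squares on
#' `ln(intensity/confluence)` versus time: `kd` is the negated slope and
#' `t1/2 = ln 2 / kd`. Growth is fitted jointly for reporting. A nonlinear
#' exponential refinement (starting from the log-linear solution) is
#' available via `nonlinear = TRUE`.
#'
#' @param series Data frame with columns `time_h`, `confluence_pct`,
#'   `tmr_intensity` (or first three columns in that order).
#' @param background Estimated background intensity; points with intensity
#'   below `3 * background` are excluded. Default 0 (no exclusion).
#' @param nonlinear Refine by nonlinear least squares on the exponential.
#' @return Object of class `kinetics_fit`: `kd_per_h`, `t_half_h`
#'   (`= ln 2 / kd` exactly), `kd_se`, `t_half_se`, `td_h` (growth),
#'   `residual_norm`, `stable` flag (no measurable decay), and
#'   `exceeds_span` flag set when the half-life is longer than the
#'   observation window (the decay is then poorly constrained and the
#'   standard error widens accordingly).
#' @export
fit_turnover <- function(series, background = 0, nonlinear = FALSE) {
  s <- as_turnover_series(series, need_intensity = TRUE)
  if (any(s$confluence_pct <= 0))
    stop_invalid("confluence must be positive wherever intensity is normalised")
  keep <- s$tmr_intensity > 3 * background
  if (any(!keep))
    warning(sprintf("%d points at or below 3x background excluded", sum(!keep)))
  s <- s[keep, , drop = FALSE]
  y <- s$tmr_intensity / s$confluence_pct
  pos <- y > 0
  if (any(!pos)) warning(sprintf("%d non-positive normalised points excluded", sum(!pos)))
  s <- s[pos, , drop = FALSE]; y <- y[pos]
  if (nrow(s) < 4L)
    stop_insufficient("fewer than 4 usable points after exclusions")
  fit <- lm(log(y) ~ s$time_h)
  kd <- -unname(coef(fit)[2])
  kd_se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  if (nonlinear) {
    resid_fun <- function(p) exp(p[1]) * exp(-p[2] * s$time_h) - y
    nl <- minpack.lm::nls.lm(c(coef(fit)[1], kd), fn = resid_fun,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    if (nl$info %in% 1:4) {
      kd <- unname(nl$par[2])
      kd_se <- tryCatch(sqrt(diag(solve(nl$hessian)))[2], error = function(e) kd_se)
    }
  }
  # slopes below numerical noise (regression round-off on a flat series)
  # count as no measurable decay
  stable <- !is.finite(kd) || kd <= sqrt(.Machine$double.eps)
  if (stable) {
    warning("no measurable decay: label appears stable over the observation span")
    kd <- 0
  }
  t_half <- if (kd > 0) log(2) / kd else Inf
  span <- diff(range(s$time_h))
  exceeds <- is.finite(t_half) && t_half > span
  if (exceeds)
    warning("half-life exceeds observation span; estimate is extrapolated")
  growth <- suppressWarnings(fit_growth(s[, c("time_h", "confluence_pct")]))
  structure(
    list(kd_per_h = kd,
         t_half_h = t_half,
         kd_se = kd_se,
         t_half_se = if (kd > 0) log(2) / kd^2 * kd_se else NA_real_,
         td_h = growth$td_h,
         residual_norm = sqrt(sum(residuals(fit)^2)),
         n_used = nrow(s), span_h = span,
         stable = stable, exceeds_span = exceeds),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Turnover fit (%d points over %g h):\n", x$n_used, x$span_h))
  cat(sprintf("  kd = %.4g 1/h, t1/2 = %.3g h (se %.2g), td = %.3g h\n",
              x$kd_per_h, x$t_half_h, x$t_half_se, x$td_h))
  if (x$stable) cat("  flag: stable (no measurable decay)\n")
  if (x$exceeds_span) cat("  flag: half-life exceeds observation span\n")
  invisible(x)
}
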