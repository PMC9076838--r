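#' Denatured fraction from a spectral intensity ratio
#'
#' Linear interpolation between the native and denatured tryptophan
#' I330/I355 baselines:
#' `fD = (ratio - ratio_native) / (ratio_denatured - ratio_native)`, clipped
#' to `[0, 1]`. Clipped points are flagged in the `"clipped"` attribute.
#'
#' @param ratio Observed intensity ratio(s).
#' @param ratio_native,ratio_denatured Baselines (must differ).
#' @return Numeric vector of denatured fractions in `[0, 1]` with a logical
#'   attribute `clipped`.
#' @export
fraction_denatured <- function(ratio, ratio_native, ratio_denatured) {
  if (ratio_native == ratio_denatured)
    stop_invalid("native and denatured baselines must differ")
  fd <- (ratio - ratio_native) / (ratio_denatured - ratio_native)
  clipped <- fd < 0 | fd > 1
  structure(pmin(pmax(fd, 0), 1), clipped = clipped)
}

#' Unfolding free energy from the denatured fraction
#'
#' Two-state relation `dG0 = -RT ln(fD / (1 - fD))` with R in kcal units.
#' Fractions outside the usable window are returned as `NA` (an
#' excluded-point signal, not an error): the transform diverges at the
#' extremes, so near-baseline points carry no free-energy information.
#'
#' @param fd Denatured fraction(s).
#' @param temperature Temperature in K.
#' @param window Usable fD interval; points outside it are excluded.
#' @return Free energies in kcal/mol (`NA` where excluded).
#' @examples
#' dg_from_fraction(0.5)      # 0 at the midpoint
#' dg_from_fraction(0.03305)  # about 2.0 kcal/mol at 298.15 K
#' @export
dg_from_fraction <- function(fd, temperature = .DEFAULT_TEMPERATURE,
                             window = c(0.02, 0.98)) {
  if (temperature <= 0) stop_invalid("`temperature` must be positive")
  if (length(window) != 2L || window[1] <= 0 || window[2] >= 1 ||
      window[1] >= window[2])
    stop_invalid("`window` must be an increasing interval inside (0, 1)")
  dg <- -.R_KCAL * temperature * log(fd / (1 - fd))
  dg[fd < window[1] | fd > window[2]] <- NA_real_
  dg
}

#' Equilibrium constant of unfolding
#'
#' `K_Unf = exp(-dG0 / RT)`: the metastability proxy relating a variant's
#' thermodynamic stability to its unfolded fraction at equilibrium.
#'
#' @param dg_water Unfolding free energy in kcal/mol.
#' @param temperature Temperature in K.
#' @return Dimensionless equilibrium constant.
#' @export
k_unfolding <- function(dg_water, temperature = .DEFAULT_TEMPERATURE) {
  if (temperature <= 0) stop_invalid("`temperature` must be positive")
  exp(-dg_water / (.R_KCAL * temperature))
}

# Baselines from the flattest ends of the curve: mean of the first/last 3
# points in urea order (constant, urea-independent baselines).
estimate_baselines <- function(urea, ratio) {
  ord <- order(urea)
  list(ratio_native = mean(ratio[ord][1:3]),
       ratio_denatured = mean(ratio[ord][length(ratio) - 2:0]))
}

#' Two-state stability fit by linear extrapolation
#'
#' Converts a urea denaturation curve to pointwise free energies
#' (`dG0 = -RT ln(fD/(1-fD))`) inside the usable fD window, then fits the
#' linear extrapolation model `dG0(urea) = dg_water - m * urea` by least
#' squares. The intercept is the unfolding free energy in water, the
#' negated slope the m-value; the midpoint `Cm = dg_water/m` and
#' `K_Unf = exp(-dg_water/RT)` are derived.
#'
#' With constant noise on the spectral ratio, the propagated dG uncertainty
#' is far from constant: it scales as `RT / (fD (1 - fD))`, roughly a
#' hundredfold larger at the window edges than at the midpoint. The default
#' `weighting = "variance"` therefore weights each point by
#' `(fD (1 - fD))^2` (inverse propagated variance); this also suppresses
#' the intercept bias that equal weights pick up from near-baseline points
#' that enter the window only when noise pushes them in. `weighting =
#' "none"` gives the plain unweighted regression; on noiseless two-state
#' data the two are identical (and exact).
#'
#' @param curve Data frame with columns `urea_M`, `ratio` (or first two
#'   columns in that order), e.g. from [simulate_denaturation_curve()].
#' @param ratio_native,ratio_denatured Baselines; if either is `NULL` both
#'   are estimated from the flattest 3 points at each end of the curve.
#' @param temperature Temperature in K.
#' @param window Usable fD interval (recorded in the fit report).
#' @param weighting `"variance"` (default) for inverse-propagated-variance
#'   weights, `"none"` for ordinary least squares.
#' @return Object of class `stability_fit`: `dg_water`, `m_value`, `cm`,
#'   `k_unf` (kcal/mol, kcal/mol/M, M, dimensionless), `r_squared`,
#'   `residuals`, `n_used`, `window`, `baselines`, `temperature`.
#' @export
stability_fit <- function(curve, ratio_native = NULL, ratio_denatured = NULL,
                          temperature = .DEFAULT_TEMPERATURE,
                          window = c(0.02, 0.98),
                          weighting = c("variance", "none")) {
  weighting <- match.arg(weighting)
  curve <- as.data.frame(curve)
  urea <- curve[["urea_M"]] %||% curve[[1]]
  ratio <- curve[["ratio"]] %||% curve[[2]]
  if (any(!is.finite(urea)) || any(!is.finite(ratio)) || any(urea < 0))
    stop_invalid("curve must contain finite ratios and non-negative urea")
  if (is.null(ratio_native) || is.null(ratio_denatured)) {
    if (length(urea) < 6L)
      stop_insufficient("need >= 6 points to estimate baselines from the curve ends")
    bl <- estimate_baselines(urea, ratio)
    ratio_native <- ratio_native %||% bl$ratio_native
    ratio_denatured <- ratio_denatured %||% bl$ratio_denatured
  }
  fd <- fraction_denatured(ratio, ratio_native, ratio_denatured)
  dg <- dg_from_fraction(fd, temperature, window)
  use <- !is.na(dg)
  if (sum(use) < 3L)
    stop_insufficient(sprintf(
      "only %d points fall in the usable fD window [%g, %g]; >= 3 required",
      sum(use), window[1], window[2]))
  w <- if (weighting == "variance") (fd[use] * (1 - fd[use]))^2 else NULL
  fit <- lm(dg[use] ~ urea[use], weights = w)
  sm <- suppressWarnings(summary(fit))  # noiseless input fits exactly
  dg_water <- unname(coef(fit)[1])
  m_value <- -unname(coef(fit)[2])
  if (m_value <= 0)
    warning("non-positive m-value: the curve is not a cooperative unfolder")
  structure(
    list(dg_water = dg_water, m_value = m_value,
         cm = dg_water / m_value,
         k_unf = k_unfolding(dg_water, temperature),
         r_squared = sm$r.squared,
         residuals = unname(residuals(fit)),
         n_used = sum(use), window = window, weighting = weighting,
         baselines = c(ratio_native = ratio_native,
                       ratio_denatured = ratio_denatured),
         temperature = temperature),
    class = "stability_fit"
  )
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf(
    "Two-state stability fit (%d points, fD window [%g, %g]):\n",
    x$n_used, x$window[1], x$window[2]))
  cat(sprintf("  dG0_water = %.3f kcal/mol, m = %.3f kcal/mol/M\n",
              x$dg_water, x$m_value))
  cat(sprintf("  Cm = %.2f M, K_Unf = %.3g (T = %.2f K), R^2 = %.4f\n",
              x$cm, x$k_unf, x$temperature, x$r_squared))
  invisible(x)
}

#' Aggregation load versus metastability regression
#'
#' Ordinary least squares of the per-variant aggregate area fraction on the
#' unfolding equilibrium constant, testing the linear relation between a
#' variant's metastability and its intracellular aggregation load.
#'
#' @param k_unf Unfolding equilibrium constants, one per variant.
#' @param area_fraction Mean aggregate area fractions, one per variant.
#' @return List of class `metastability_fit`: `slope`, `intercept`,
#'   `r_squared`, `slope_se`, `degenerate` (TRUE when all `k_unf` coincide
#'   and the slope is undefined).
#' @export
metastability_regression <- function(k_unf, area_fraction) {
  if (length(k_unf) != length(area_fraction) || length(k_unf) < 3L)
    stop_insufficient("need >= 3 matching (k_unf, area_fraction) points")
  if (sd(k_unf) == 0) {
    warning("all k_unf identical: slope is undefined")
    return(structure(list(slope = NA_real_, intercept = mean(area_fraction),
                          r_squared = NA_real_, slope_se = NA_real_,
                          degenerate = TRUE),
                     class = "metastability_fit"))
  }
  fit <- lm(area_fraction ~ k_unf)
  sm <- suppressWarnings(summary(fit))
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         slope_se = unname(sm$coefficients[2, 2]),
         degenerate = FALSE),
    class = "metastability_fit"
  )
}
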