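#' Simulate an FCS autocorrelation curve
#'
#' Generates `G(tau) - 1` for a mixture of freely diffusing species in a 3-D
#' Gaussian confocal volume. Each species is specified by its hydrodynamic
#' radius; its diffusion coefficient follows from the Stokes-Einstein relation
#' at the given temperature and viscosity, and its diffusion time from the
#' beam waist, `tau_D = w0^2 / (4 D)`. Noise is multiplicative Gaussian (FCS
#' noise scales with the correlation amplitude).
#'
#' @param species List of `c(Rh_nm, fraction)` pairs or a 2-column matrix;
#'   amplitude fractions must sum to 1.
#' @param n_mean Mean number of particles in the focal volume (sets the
#'   amplitude `1/n_mean`).
#' @param w0 Lateral beam waist in micrometres.
#' @param kappa Axial-to-lateral aspect ratio of the focal volume.
#' @param temperature Temperature in K.
#' @param viscosity Solvent viscosity in Pa s.
#' @param lag_grid Strictly increasing lag times in seconds.
#' @param noise_sd_rel Relative (multiplicative) Gaussian noise sd; 0 for a
#'   noiseless curve.
#' @param seed Optional integer seed.
#' @return A data frame of class `fcs_curve` with columns `lag_s`,
#'   `g_minus_1`; the generating parameters are attached as attribute `truth`.
#' @export
simulate_fcs_curve <- function(species, n_mean, w0 = 0.25, kappa = 5,
                               temperature = .DEFAULT_TEMPERATURE,
                               viscosity = .DEFAULT_VISCOSITY,
                               lag_grid = 10^seq(-6, 1, length.out = 64),
                               noise_sd_rel = 0, seed = NULL) {
  sp <- as_components(species)  # same validation: positive sizes, fractions sum to 1
  if (temperature <= 0 || viscosity <= 0)
    stop_invalid("`temperature` and `viscosity` must be positive")
  if (n_mean <= 0) stop_invalid("`n_mean` must be positive")
  if (is.unsorted(lag_grid, strictly = TRUE) || any(lag_grid <= 0))
    stop_invalid("`lag_grid` must be strictly increasing and positive")
  d_um2s <- stokes_einstein_diffusion(sp[, 1], temperature, viscosity)
  tau_d <- w0^2 / (4 * d_um2s)
  g <- fcs_model(lag_grid, n_mean, cbind(tau_d, sp[, 2]), kappa)
  g_obs <- with_seed(seed, g * (1 + rnorm(length(g), 0, noise_sd_rel)))
  structure(
    data.frame(lag_s = lag_grid, g_minus_1 = g_obs),
    truth = list(rh_nm = sp[, 1], fraction = sp[, 2], n_mean = n_mean,
                 w0 = w0, kappa = kappa, tau_d = tau_d, d_um2s = d_um2s,
                 temperature = temperature, viscosity = viscosity),
    class = c("fcs_curve", "data.frame")
  )
}

#' Simulate a two-state urea denaturation curve
#'
#' The denatured fraction follows the two-state law
#' `fD(urea) = 1 / (1 + exp(dG(urea) / RT))` with the linear free-energy
#' dependence `dG(urea) = dg_water - m_value * urea`; the observed tryptophan
#' intensity ratio (I330/I355) interpolates linearly between the native and
#' denatured baselines, plus additive Gaussian noise.
#'
#' @param dg_water Unfolding free energy in water, kcal/mol.
#' @param m_value Linear urea dependence of the free energy, kcal/mol/M (> 0).
#' @param ratio_native,ratio_denatured Baseline intensity ratios of the folded
#'   and denatured states (must differ).
#' @param urea_grid Urea concentrations in M.
#' @param noise_sd Additive Gaussian noise sd on the ratio.
#' @param temperature Temperature in K.
#' @param seed Optional integer seed.
#' @return A data frame of class `denaturation_curve` with columns `urea_M`,
#'   `ratio`; generating parameters attached as attribute `truth`.
#' @export
simulate_denaturation_curve <- function(dg_water, m_value,
                                        ratio_native = 1.9,
                                        ratio_denatured = 0.9,
                                        urea_grid = seq(0, 8, by = 0.5),
                                        noise_sd = 0,
                                        temperature = .DEFAULT_TEMPERATURE,
                                        seed = NULL) {
  if (m_value <= 0) stop_invalid("`m_value` must be positive")
  if (ratio_native == ratio_denatured)
    stop_invalid("native and denatured baselines must differ")
  if (!length(urea_grid)) stop_invalid("`urea_grid` must be non-empty")
  if (any(urea_grid < 0)) stop_invalid("urea concentrations must be >= 0")
  if (temperature <= 0) stop_invalid("`temperature` must be positive")
  rt <- .R_KCAL * temperature
  fd <- 1 / (1 + exp((dg_water - m_value * urea_grid) / rt))
  ratio <- ratio_native + fd * (ratio_denatured - ratio_native)
  ratio <- with_seed(seed, ratio + rnorm(length(ratio), 0, noise_sd))
  structure(
    data.frame(urea_M = urea_grid, ratio = ratio),
    truth = list(dg_water = dg_water, m_value = m_value,
                 ratio_native = ratio_native, ratio_denatured = ratio_denatured,
                 temperature = temperature, fd = fd),
    class = c("denaturation_curve", "data.frame")
  )
}

#' Simulate a growth / pulse-chase turnover time series
#'
#' Confluence grows exponentially, `conf_t = conf0 * 2^(t/td)`. The pulse
#' label is conserved across divisions, so its total intensity tracks growth
#' while being degraded first-order:
#' `intensity_t = intensity0 * 2^(t/td) * exp(-ln 2 * t / half_life)`; the
#' per-cell label (`intensity / confluence`) therefore decays with the given
#' half-life, which is what confluence normalisation recovers.
#'
#' @param doubling_time Cell doubling time td in hours.
#' @param half_life Label half-life in hours; `Inf` for a non-degraded label.
#' @param duration Observation span in hours.
#' @param interval Sampling interval in hours (default 4, the imaging cadence).
#' @param conf0 Initial confluence in percent (> 0).
#' @param intensity0 Initial integrated label intensity (arbitrary units).
#' @param noise_sd_rel Relative Gaussian noise sd applied to the intensity.
#' @param seed Optional integer seed.
#' @return A data frame of class `turnover_series` with columns `time_h`,
#'   `confluence_pct`, `tmr_intensity`; truth attached as attribute.
#' @export
simulate_growth_turnover <- function(doubling_time, half_life, duration = 96,
                                     interval = 4, conf0 = 5,
                                     intensity0 = 1000, noise_sd_rel = 0,
                                     seed = NULL) {
  if (doubling_time <= 0) stop_invalid("`doubling_time` must be positive")
  if (half_life <= 0) stop_invalid("`half_life` must be positive (Inf allowed)")
  if (interval <= 0 || interval > duration)
    stop_invalid("`interval` must be positive and no longer than `duration`")
  if (conf0 <= 0) stop_invalid("`conf0` must be positive")
  if (intensity0 <= 0) stop_invalid("`intensity0` must be positive")
  t <- seq(0, duration, by = interval)
  conf <- conf0 * 2^(t / doubling_time)
  decay <- if (is.finite(half_life)) exp(-log(2) * t / half_life) else 1
  intensity <- intensity0 * 2^(t / doubling_time) * decay
  intensity <- with_seed(seed,
                         intensity * (1 + rnorm(length(t), 0, noise_sd_rel)))
  structure(
    data.frame(time_h = t, confluence_pct = conf, tmr_intensity = intensity),
    truth = list(doubling_time = doubling_time, half_life = half_life,
                 conf0 = conf0, intensity0 = intensity0),
    class = c("turnover_series", "data.frame")
  )
}
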