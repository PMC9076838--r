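#' Pure-diffusion FCS correlation model
#'
#' `G(tau) - 1` for free 3-D diffusion of one or more species through a
#' Gaussian confocal volume (no triplet term):
#' \deqn{G(\tau)-1 = \frac{1}{N}\sum_i f_i\,(1+\tau/\tau_{D,i})^{-1}
#'   (1+\tau/(\kappa^2\tau_{D,i}))^{-1/2}}
#'
#' @param lag Lag times in seconds.
#' @param n_mean Mean occupancy of the focal volume (amplitude is `1/n_mean`).
#' @param species List of `c(tau_d_s, fraction)` pairs or a 2-column matrix;
#'   fractions must sum to 1 (tolerance 1e-9).
#' @param kappa Axial ratio of the focal volume.
#' @return Numeric vector of `G(tau) - 1`.
#' @examples
#' fcs_model(1e-7, n_mean = 5, species = list(c(3e-3, 1)))  # ~ 1/5
#' @export
fcs_model <- function(lag, n_mean, species, kappa = 5) {
  sp <- as_components(species)  # tau_d > 0, fractions sum to 1
  if (n_mean <= 0 || kappa <= 0)
    stop_invalid("`n_mean` and `kappa` must be positive")
  g <- 0
  for (i in seq_len(nrow(sp))) {
    x <- lag / sp[i, 1]
    g <- g + sp[i, 2] / ((1 + x) * sqrt(1 + x / kappa^2))
  }
  g / n_mean
}

#' Calibrate the focal volume against a reference dye
#'
#' Given the fitted diffusion time of a reference dye of known diffusion
#' coefficient (Atto655-COOH, D = 425 um^2/s in water at 25 C, is the
#' conventional standard), returns the lateral beam waist
#' `w0 = sqrt(4 * d_ref * tau_d_ref)`.
#'
#' @param tau_d_ref Fitted diffusion time of the reference dye, seconds.
#' @param d_ref Reference diffusion coefficient, um^2/s. Default 425.
#' @return Beam waist w0 in micrometres.
#' @examples
#' calibrate_focal_volume(36.8e-6)  # about 0.25 um
#' @export
calibrate_focal_volume <- function(tau_d_ref, d_ref = 425) {
  if (tau_d_ref <= 0 || d_ref <= 0)
    stop_invalid("`tau_d_ref` and `d_ref` must be positive")
  sqrt(4 * d_ref * tau_d_ref)
}

#' Diffusion coefficient from a diffusion time
#'
#' @param tau_d Diffusion time in seconds.
#' @param w0 Beam waist in micrometres.
#' @return D in um^2/s (`w0^2 / (4 tau_d)`).
#' @export
diffusion_from_tau <- function(tau_d, w0) {
  if (any(tau_d <= 0) || w0 <= 0) stop_invalid("inputs must be positive")
  w0^2 / (4 * tau_d)
}

#' Stokes-Einstein hydrodynamic radius
#'
#' `Rh = kB T / (6 pi eta D)` for a sphere diffusing in a continuum solvent.
#'
#' @param d Diffusion coefficient in um^2/s.
#' @param temperature Temperature in K.
#' @param viscosity Viscosity in Pa s.
#' @return Hydrodynamic radius in nm.
#' @examples
#' stokes_einstein_radius(425)   # Atto655: ~0.58 nm
#' stokes_einstein_radius(5.11)  # 48 nm aggregate
#' @export
stokes_einstein_radius <- function(d, temperature = .DEFAULT_TEMPERATURE,
                                   viscosity = .DEFAULT_VISCOSITY) {
  if (any(d <= 0) || temperature <= 0 || viscosity <= 0)
    stop_invalid("inputs must be positive")
  .kB * temperature / (6 * pi * viscosity * (d * 1e-12)) * 1e9
}

#' @rdname stokes_einstein_radius
#' @param rh_nm Hydrodynamic radius in nm (inverse direction: returns D in
#'   um^2/s).
#' @export
stokes_einstein_diffusion <- function(rh_nm, temperature = .DEFAULT_TEMPERATURE,
                                      viscosity = .DEFAULT_VISCOSITY) {
  if (any(rh_nm <= 0) || temperature <= 0 || viscosity <= 0)
    stop_invalid("inputs must be positive")
  .kB * temperature / (6 * pi * viscosity * (rh_nm * 1e-9)) * 1e12
}

validate_fcs_curve <- function(curve) {
  curve <- as.data.frame(curve)
  lag <- curve[[intersect(c("lag_s", "lag"), names(curve))[1] %||% 1L]]
  g <- curve[[intersect(c("g_minus_1", "g"), names(curve))[1] %||% 2L]]
  if (is.null(lag) || is.null(g)) lag <- curve[[1]]
  if (is.null(g)) g <- curve[[2]]
  if (any(!is.finite(lag)) || any(!is.finite(g)))
    stop(errorCondition("curve contains non-finite values",
                        class = c("flimaggr_invalid_input", "error", "condition")))
  if (length(lag) < 10L || is.unsorted(lag, strictly = TRUE) || any(lag <= 0))
    stop(errorCondition("need >= 10 strictly increasing positive lag times",
                        class = c("flimaggr_invalid_input", "error", "condition")))
  if (log10(lag[length(lag)] / lag[1]) < 3)
    stop(errorCondition("lag times must span at least 3 decades",
                        class = c("flimaggr_invalid_input", "error", "condition")))
  if (max(g) <= 0)
    stop(errorCondition("curve amplitude is non-positive",
                        class = c("flimaggr_invalid_input", "error", "condition")))
  data.frame(lag_s = lag, g_minus_1 = g)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Fit a 3-D diffusion model to an FCS curve
#'
#' Weighted least squares of [fcs_model()] against a measured `G(tau) - 1`
#' curve. By default residuals are relative (model/data - 1), reflecting the
#' amplitude scaling of FCS noise; absolute residuals are available via
#' `relative_residuals = FALSE`. The two-species fit keeps the amplitude
#' fractions on the simplex through a single logit parameter and orders
#' species by diffusion time, ascending.
#'
#' @param curve Data frame with columns `lag_s`, `g_minus_1` (or first two
#'   columns in that order), e.g. from [simulate_fcs_curve()].
#' @param n_species 1 or 2.
#' @param kappa Axial ratio; fixed unless `fit_kappa = TRUE`.
#' @param fit_kappa Also fit the axial ratio (rarely identifiable).
#' @param init Optional named list overriding starting values (`n_mean`,
#'   `tau_d` vector, `fraction`).
#' @param relative_residuals Use multiplicative residuals (default).
#' @param w0 Beam waist in um from [calibrate_focal_volume()]; when supplied,
#'   fitted diffusion times are converted to diffusion coefficients and
#'   Stokes-Einstein radii under `temperature` / `viscosity`.
#' @param temperature,viscosity Conditions for the size conversion.
#' @return Object of class `diffusion_fit`: `n_mean`, `species` (data frame
#'   `tau_d_s`, `fraction`, `d_um2s`, `rh_nm`), `kappa`, `residual_norm`,
#'   `converged`, `degenerate`, `conditions`.
#' @export
fit_fcs <- function(curve, n_species = 1, kappa = 5, fit_kappa = FALSE,
                    init = NULL, relative_residuals = TRUE, w0 = NULL,
                    temperature = .DEFAULT_TEMPERATURE,
                    viscosity = .DEFAULT_VISCOSITY) {
  cv <- validate_fcs_curve(curve)
  n_species <- as.integer(n_species)
  if (!n_species %in% 1:2) stop_invalid("`n_species` must be 1 or 2")
  lag <- cv$lag_s; g <- cv$g_minus_1

  # starting values: amplitude from the plateau, tau_d from the half-decay lag
  n0 <- init$n_mean %||% (1 / max(mean(head(g, 3)), 1e-12))
  gh <- max(g) / 2
  i_half <- which(g <= gh)[1] %||% length(lag)
  tau0 <- init$tau_d %||% {
    t_half <- lag[max(i_half, 2L)]
    if (n_species == 1) t_half else c(t_half / 10, t_half * 10)
  }
  f0 <- init$fraction %||% rep(1 / n_species, n_species)

  # parameters: log n_mean, log tau_d (ascending), logit f1, [log kappa]
  p0 <- c(log(n0), log(sort(tau0)))
  if (n_species == 2) p0 <- c(p0, stats::qlogis(f0[1]))
  if (fit_kappa) p0 <- c(p0, log(kappa))

  unpack <- function(p) {
    nm <- exp(p[1])
    td <- exp(p[2:(1 + n_species)])
    fr <- if (n_species == 2) {
      f1 <- stats::plogis(p[2 + n_species]); c(f1, 1 - f1)
    } else 1
    kp <- if (fit_kappa) exp(p[length(p)]) else kappa
    list(n_mean = nm, tau_d = td, fraction = fr, kappa = kp)
  }
  resid_fun <- function(p) {
    q <- unpack(p)
    m <- fcs_model(lag, q$n_mean, cbind(q$tau_d, q$fraction), q$kappa)
    if (relative_residuals) m / g - 1 else m - g
  }
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, maxiter = 1000)
  fit <- minpack.lm::nls.lm(p0, fn = resid_fun, control = ctl)
  if (!fit$info %in% 1:4)
    stop_fit_failure(sprintf("FCS fit did not converge (nls.lm info %d: %s)",
                             fit$info, fit$message))
  q <- unpack(fit$par)
  ord <- order(q$tau_d)
  tau_d <- q$tau_d[ord]; fraction <- rep(q$fraction, length.out = n_species)[ord]
  degenerate <- n_species == 2 && abs(log(tau_d[2] / tau_d[1])) < 0.05
  if (degenerate)
    warning("two-species fit is degenerate: diffusion times coincide, fractions are unidentifiable")
  d_um2s <- rh_nm <- rep(NA_real_, n_species)
  if (!is.null(w0)) {
    d_um2s <- diffusion_from_tau(tau_d, w0)
    rh_nm <- stokes_einstein_radius(d_um2s, temperature, viscosity)
  }
  structure(
    list(n_mean = q$n_mean,
         species = data.frame(tau_d_s = tau_d, fraction = fraction,
                              d_um2s = d_um2s, rh_nm = rh_nm),
         kappa = q$kappa,
         residual_norm = sqrt(sum(resid_fun(fit$par)^2)),
         relative_residuals = relative_residuals,
         converged = TRUE, degenerate = degenerate,
         conditions = list(w0 = w0, temperature = temperature,
                           viscosity = viscosity)),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("FCS diffusion fit: N = %.3g, kappa = %.3g, residual norm %.3g\n",
              x$n_mean, x$kappa, x$residual_norm))
  sp <- x$species
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  species %d: tau_D = %.4g s (f = %.3f)", i,
                sp$tau_d_s[i], sp$fraction[i]))
    if (!is.na(sp$rh_nm[i]))
      cat(sprintf(", D = %.4g um^2/s, Rh = %.4g nm", sp$d_um2s[i], sp$rh_nm[i]))
    cat("\n")
  }
  invisible(x)
}

#' Scattering vector magnitude for DLS
#'
#' `q = 4 pi n sin(theta/2) / lambda`.
#'
#' @param theta_deg Scattering angle in degrees.
#' @param lambda_nm Laser wavelength in nm.
#' @param n_medium Refractive index of the solvent.
#' @return q in 1/m.
#' @export
dls_q <- function(theta_deg = 173, lambda_nm = 633, n_medium = 1.33) {
  if (theta_deg <= 0 || theta_deg > 180 || lambda_nm <= 0 || n_medium <= 0)
    stop_invalid("invalid scattering geometry")
  4 * pi * n_medium * sin(theta_deg / 2 * pi / 180) / (lambda_nm * 1e-9)
}

#' Fit a single-exponential DLS correlation decay
#'
#' Fits `g2(tau) - 1 = beta * exp(-2 Gamma tau)` and converts the decay rate
#' to a diffusion coefficient, `D = Gamma / q^2`, and a hydrodynamic diameter
#' `Dh = 2 Rh` via Stokes-Einstein.
#'
#' @param delay_s Delay times in seconds.
#' @param g2_minus_1 Intensity correlation minus baseline.
#' @param q Scattering vector in 1/m (see [dls_q()]).
#' @param temperature,viscosity Conditions for the size conversion.
#' @return Object of class `dls_fit`: `beta`, `gamma_s` (1/s), `d_um2s`,
#'   `rh_nm`, `dh_nm`, `residual_norm`.
#' @export
dls_fit <- function(delay_s, g2_minus_1, q = dls_q(),
                    temperature = .DEFAULT_TEMPERATURE,
                    viscosity = .DEFAULT_VISCOSITY) {
  if (length(delay_s) != length(g2_minus_1) || length(delay_s) < 4L)
    stop_invalid("need >= 4 matching (delay, correlation) points")
  if (q <= 0) stop_invalid("`q` must be positive")
  beta0 <- max(g2_minus_1)
  if (beta0 <= 0) stop_fit_failure("correlation curve has no positive amplitude")
  pos <- which(g2_minus_1 > 0.05 * beta0)
  if (length(pos) < 3L) stop_fit_failure("too few points above the noise floor")
  sl <- coef(lm(log(g2_minus_1[pos]) ~ delay_s[pos]))
  if (!is.finite(sl[2]) || sl[2] >= 0)
    stop_fit_failure("correlation curve does not decay")
  resid_fun <- function(p)
    exp(p[1]) * exp(-2 * exp(p[2]) * delay_s) - g2_minus_1
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, maxiter = 1000)
  fit <- minpack.lm::nls.lm(c(sl[1], log(-sl[2] / 2)), fn = resid_fun,
                            control = ctl)
  if (!fit$info %in% 1:4)
    stop_fit_failure(sprintf("DLS fit did not converge (info %d)", fit$info))
  fit$par <- unname(fit$par)
  gamma <- exp(fit$par[2])
  d_m2s <- gamma / q^2
  rh <- stokes_einstein_radius(d_m2s * 1e12, temperature, viscosity)
  structure(
    list(beta = exp(fit$par[1]), gamma_s = gamma, d_um2s = d_m2s * 1e12,
         rh_nm = rh, dh_nm = 2 * rh,
         residual_norm = sqrt(sum(resid_fun(fit$par)^2)),
         conditions = list(q = q, temperature = temperature,
                           viscosity = viscosity)),
    class = "dls_fit"
  )
}

#' @export
print.dls_fit <- function(x, ...) {
  cat(sprintf("DLS fit: Gamma = %.4g 1/s, D = %.4g um^2/s, Dh = %.4g nm\n",
              x$gamma_s, x$d_um2s, x$dh_nm))
  invisible(x)
}
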