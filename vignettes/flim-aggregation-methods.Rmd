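---
title: "Methods: lifetime-based aggregation quantification and its companion fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime-based aggregation quantification and its companion fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimaggr)
```

# The measurement problem

A solvatochromic fluorophore attached to a metastable reporter protein
changes its excited-state lifetime with the rigidity and polarity of its
surroundings: covalently bound to the natively folded reporter it decays at
about 3.3 ns, while inside aggregated material the lifetime rises into a
4.9–7.6 ns plateau. Imaging that lifetime pixel by pixel (FLIM) therefore
maps the aggregation state of the reporter across a cell, free from the
intensity calibration and photobleaching problems of intensity-based
readouts. `flimaggr` implements the downstream quantification: lifetime
estimation from raw photon-arrival histograms, puncta detection and
per-cell aggregation metrics, and the companion in vitro measurements
(particle sizing by FCS/DLS, two-state folding stability, pulse-chase
turnover) that tie the imaging to biophysics.

Because raw live-cell data are instrument-bound, every stage is paired with
a synthetic generator with known ground truth; the package's tests are
round trips through generator and estimator.

# Mean-arrival lifetime estimation

The per-pixel estimator is the mean-arrival-channel (FastFLIM) method: the
average TCSPC channel of the decay minus the average TCSPC channel of the
instrument response, multiplied by the channel width,

$$\hat\tau = \Delta t\,\left(\frac{\sum_i i\,d_i}{\sum_i d_i}
            - \frac{\sum_i i\,r_i}{\sum_i r_i}\right),$$

with $d_i$ the decay counts, $r_i$ the IRF counts and $\Delta t$ the bin
width. Both centroids use the left-edge bin index, so the half-bin offset
cancels in the subtraction; only the difference is meaningful.

Two properties matter in practice:

* **Truncation bias.** Photons are observed within one repetition period
  $T$ (50 ns at 20 MHz). For a mono-exponential decay the estimator
  converges to the truncated mean
  $\tau - T e^{-T/\tau}/(1 - e^{-T/\tau})$, not to $\tau$: negligible at
  3.3 ns ($<2\times10^{-5}$ ns) but visible at 7.6 ns (estimate 7.53 ns).
  `truncated_exp_mean()` gives the closed form; the bias is reported, not
  corrected, because the reference implementation does not correct it. An
  optional inversion is available via `correct_truncation = TRUE` and is
  exact for mono-exponential decays.
* **Photon threshold.** The single-pixel standard error is roughly
  $\tau/\sqrt{N}$. The default `min_photons = 100` puts it near
  0.33 ns at 3.3 ns — enough to separate the native population from the
  >5 ns aggregate regime. Pixels below the threshold are marked invalid
  (`NA`) rather than reported; no threshold value is canonical, so it is a
  visible, recorded parameter.

Dark-count background subtraction is not implemented (the acquisition it
models does not describe one); strongly scattering samples would need it.

# Aggregate detection

Aggregates appear as puncta of long-lifetime pixels. The detector is
deliberately simple and fully specified — a lifetime threshold plus
connected components — rather than a reimplementation of any particular
GUI tool whose internals are unpublished:

1. aggregate pixels: valid pixels with $\hat\tau$ > `lifetime_threshold`
   (default 5.0 ns) inside a labelled cell;
2. particles: connected components (default 8-connectivity) of aggregate
   pixels within a single cell — components spanning a boundary are split
   by the cell labels;
3. particles smaller than `min_particle_area` (default 4 px²) are
   discarded as shot-noise speckle.

Per-cell particle areas sum to the cell's aggregate area exactly, by
construction. The headline metrics are the percentage of cells with at
least one particle and the mean aggregate area fraction; both are monotone
in the underlying aggregate load, which the test suite checks against the
generator. Cell segmentation is an *input* (a label image), not a stage:
inventing a segmentation method would add an uncontrolled error source,
and synthetic masks are exact.

Invalid pixels are excluded from both the aggregate mask and the cell
area — thresholding an undefined lifetime is meaningless, and counting
such pixels in the denominator would make the area fraction depend on
exposure.

# FCS, calibration, and particle sizing

Autocorrelation curves are fitted with the pure 3-D diffusion model

$$G(\tau)-1 = \frac{1}{N}\sum_i f_i\,
  \left(1+\frac{\tau}{\tau_{D,i}}\right)^{-1}
  \left(1+\frac{\tau}{\kappa^2\tau_{D,i}}\right)^{-1/2},$$

without a triplet term. The beam waist comes from a reference-dye
calibration, $w_0 = \sqrt{4 D_{\rm ref}\,\tau_{D,\rm ref}}$ with
$D_{\rm ref} = 425\ \mu m^2/s$ (Atto655-COOH in water at 25 °C), and
fitted diffusion times convert to sizes through Stokes–Einstein,
$R_h = k_B T / (6\pi\eta D)$. Defaults are 298.15 K and
$\eta = 0.00089$ Pa·s, the calibration conditions. The axial ratio
$\kappa$ is fixed at 5 — a typical confocal value, not separately
identifiable from a single curve — and can be freed or changed.

Numerical choices: residuals are relative (model/data − 1) by default
because FCS noise scales with the correlation amplitude; parameters are
fitted on log scale with the two-species amplitude pair parameterised by a
single logit, keeping the simplex constraint exact; the two-species fit is
initialised from the one-species solution, which also guarantees its
residual never exceeds the one-species residual. Two-species fits whose
diffusion times collapse onto each other (ratio within 5 %) are flagged
degenerate — the fractions are then unidentifiable.

DLS correlation decays are fitted as $\beta e^{-2\Gamma\tau}$,
$D = \Gamma/q^2$, $D_h = 2R_h$, with the scattering vector from
$q = 4\pi n \sin(\theta/2)/\lambda$ (defaults: 173°, 633 nm, n = 1.33).

# Two-state folding thermodynamics

Tryptophan fluorescence shifts red on unfolding, so the intensity ratio
I330/I355 interpolates between a native and a denatured baseline; the
denatured fraction $f_D$ converts pointwise to a free energy
$\Delta G^0 = -RT\ln(f_D/(1-f_D))$ and the linear extrapolation model
$\Delta G^0({\rm urea}) = \Delta G^0_{\rm water} - m\,[{\rm urea}]$ is
fitted by least squares. $R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹ and
$T = 298.15$ K by default (the experiments are performed at 25 °C; the
temperature is configurable). `K_Unf = exp(-dG/RT)` links stability to the
aggregation metrics via `metastability_regression()`.

Two choices deserve justification:

* **Usable window.** The transform diverges at $f_D \to 0, 1$; points
  outside $f_D \in [0.02, 0.98]$ are excluded (recorded in the report).
  The window is a variance control, not a physical parameter.
* **Weighted regression.** With constant noise on the ratio, the
  propagated dG noise scales as $RT/(f_D(1-f_D))$ — two orders of
  magnitude larger at the window edges than at the midpoint. The default
  fit weights each point by $(f_D(1-f_D))^2$, the inverse propagated
  variance. Besides efficiency, this suppresses a systematic intercept
  bias of unweighted regression: near-baseline points clear the window
  preferentially when noise pushes them inward, so their dG values are
  one-sidedly wrong, and equal weights hand these worst points full
  influence (at $\Delta G^0 = 5.6$ kcal/mol, m = 1, 1 % ratio noise the
  unweighted intercept is low by ≈0.4 kcal/mol; the weighted fit is low
  by <0.15). On noiseless data both are identical and exact, which the
  round-trip tests assert. Plain OLS remains available
  (`weighting = "none"`).

Baselines are treated as urea-independent constants, supplied by the user
or estimated from the flattest three points at each end of the curve; a
sloped-baseline model is out of scope. Fitting the raw ratio sigmoid
directly would be an equivalent route on two-state data; the pointwise
transform is implemented because it exposes the intermediate dG values the
linear-extrapolation plot is built from.

# Growth and turnover kinetics

Confluence grows as $\%{\rm conf}_t = \%{\rm conf}_{t_0} 2^{t/t_d}$; the
doubling time is fitted by least squares on $\log_2$ confluence. Pulse
labels are conserved across divisions, so the label intensity must be
divided by confluence before fitting the first-order decay
$y_t = y_0 e^{-k_d t}$, giving $t_{1/2} = \ln 2 / k_d$ (the identity
$t_{1/2} k_d = \ln 2$ holds exactly in every report). The decay equation
is fitted log-linearly by default: exact on noiseless data, convex, no
starting values; a nonlinear refinement is available. Points below three
times an estimated background are excluded (default background 0, i.e. no
exclusion). Half-lives longer than the observation span are reported but
flagged `exceeds_span` — they are extrapolations, and their standard
errors widen accordingly. Numerically flat series (slope below machine
noise) are flagged `stable` with $k_d = 0$.

# The synthetic generators

Each generator is the measurable inverse of its fitting stage: noiseless
output must round-trip to exact parameter recovery, which the test suite
enforces for every module.

* **TCSPC decays** (`simulate_tcspc()`): arrival = Gaussian IRF draw +
  exponential decay draw, wrapped modulo the repetition period and binned.
  Defaults: 50 ns window (20 MHz), 0.016 ns bins (3125 channels), IRF
  FWHM 0.2 ns. The IRF is modelled Gaussian because only "scattered
  light" is specified for its recording; the centre (default 2 ns) is
  arbitrary and cancels in the estimator. Simulated decays are validated
  against the analytic exGaussian-modulo-window distribution by
  chi-square goodness of fit.
* **FLIM scenes** (`simulate_flim_scene()`): non-overlapping ellipsoidal
  cells on empty background; per-pixel native lifetimes
  N(3.3 ns, 0.05 ns); puncta with lifetimes drawn Uniform(4.9, 7.6) ns —
  only the range of the aggregate plateau is characterised, so a uniform
  draw is an explicit stand-in, not an inference. Aggregate pixels are
  2× brighter by default (the dye is dim on the non-aggregated reporter;
  the true ratio is unreported). Scene cubes default to 0.2 ns bins to
  keep a 96×96 scene around 2 million counters; the estimator's IRF
  subtraction cancels the coarse binning, and the tests confirm mode
  recovery within 0.05 ns.
* **FCS curves** are generated at the correlation level (no photon-trace
  simulation) with multiplicative Gaussian noise; **denaturation curves**
  and **growth/turnover series** follow the closed-form models above, the
  latter sampled every 4 h as in automated-incubator imaging.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: detector afterpulsing and dead time, triplet
photophysics, dark counts and autofluorescence background, sloped
denaturation baselines, cell-cycle–dependent growth, out-of-focus light,
and any segmentation error (cell masks are exact by construction). The
detector guarantees (precision = recall = 1) hold under high signal-to-noise
conditions — puncta at ≥6 ns on a ≤3.5 ns background with ≥500
photons/pixel — not at arbitrary contrast.

# Problem sizes and determinism

Test and pipeline scenes are 48–96 px square with 2–4 cells and 100–250
TCSPC bins; single-decay checks use 10⁶ photons and the full 3125-bin
resolution; noise studies use 20–50 seeded replicates. These sizes make
the full round-trip suite complete in a few minutes on one CPU while
keeping every statistical check comfortably powered. All randomness flows
through per-call seeds (`with_seed` restores the caller's RNG state), and
the pipeline manifest records seed, config hash and per-artifact
checksums; identical config and seed reproduce identical checksums.

# Known limitations

* The mean-arrival estimator is unbiased only in the mono-exponential
  sense; for mixtures it returns the photon-weighted mean of (truncated)
  component lifetimes, which is the intended behaviour of the method but
  not a decomposition.
* Counts are stored in 16-bit TIFF (exact up to 65535 per bin per pixel);
  lifetime maps in 32-bit float TIFF scaled by the repetition period
  (≤1e-6 relative quantisation).
* No proprietary instrument formats are read; conversion to TIFF + JSON
  sidecar (or CSV) is up to the user.
* 3-D detection, particle tracking across timepoints, wavelet spot
  enhancement, triplet-state FCS terms and cumulant DLS polydispersity are
  out of scope.
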