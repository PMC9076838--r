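# flimaggr

Quantitative analysis of protein aggregation monitored with a
fluorescence-lifetime probe, for cell biologists and biophysicists working
with metastable reporter proteins (e.g. destabilised HaloTag variants
carrying a solvatochromic dye). The dye's lifetime reports the probe's
folding state — ~3.3 ns when natively folded, 4.9–7.6 ns inside
aggregates — so lifetime imaging (FLIM) maps aggregation across live
cells, and a handful of companion biophysical measurements connect that
map to particle sizes, folding stability and protein turnover.

The package implements, with a synthetic ground-truth generator for every
stage:

- **Lifetime estimation** from TCSPC photon-count cubes by the
  mean-arrival-channel method:
  `τ̂ = Δt · (decay centroid − IRF centroid)`, with the finite-window
  truncation bias `τ − T·e^(−T/τ)/(1 − e^(−T/τ))` reported in closed form.
- **Aggregate quantification**: lifetime threshold (default > 5 ns) +
  connected components within cells; per-cell area fractions, % cells
  with aggregates, particle-size distributions.
- **FCS / DLS particle sizing**: the pure 3-D diffusion model
  `G(τ)−1 = (1/N)·Σ fᵢ(1+τ/τD,ᵢ)⁻¹(1+τ/(κ²τD,ᵢ))^(−1/2)`, reference-dye
  focal-volume calibration (`w₀ = √(4·D_ref·τD,ref)`, Atto655 D = 425
  µm²/s), and Stokes–Einstein conversion `Rh = kB·T/(6πηD)`.
- **Two-state folding thermodynamics**: `ΔG⁰ = −RT·ln(fD/(1−fD))`,
  linear extrapolation `ΔG⁰(urea) = ΔG⁰_water − m·[urea]`, and
  `K_Unf = exp(−ΔG⁰/RT)` for the metastability–aggregation regression.
- **Growth and pulse-chase turnover**: `conf_t = conf₀·2^(t/td)` and the
  confluence-normalised decay `y_t = y₀·e^(−kd·t)`, `t½ = ln2/kd`.

## Worked example

```r
library(flimaggr)

# a synthetic field of view: 4 cells, 2 aggregate puncta each
scene <- simulate_flim_scene(scene_spec(seed = 7))
irf   <- simulate_irf(5e5, rep_period = 50, bin_width = 0.2, seed = 8)
img   <- lifetime_image(scene$stack, irf, min_photons = 100)
img
#> Lifetime image: 96 x 96 px, 2788 valid (min 100 photons); tau 2.79-7.58 ns (median 3.32)

detect_aggregates(img, scene$truth$cell_labels)
#> Aggregate report: 4 cells, 6 particles (threshold 5.00 ns, min area 4 px, 8-connectivity)
#>   100.0% of cells with aggregates; mean area fraction 0.1316

# FCS sizing of a 48 nm aggregate at 1% curve noise
curve <- simulate_fcs_curve(list(c(48, 1)), n_mean = 5, w0 = 0.25,
                            noise_sd_rel = 0.01, seed = 9)
fit_fcs(curve, w0 = 0.25)
#> FCS diffusion fit: N = 5, kappa = 5, residual norm 0.0782
#>   species 1: tau_D = 0.003055 s (f = 1.000), D = 5.114 um^2/s, Rh = 47.98 nm

# folding stability of a mildly destabilised variant (true dG0 = 2.0)
denat <- simulate_denaturation_curve(2.0, 1.0, noise_sd = 0.01, seed = 10)
stability_fit(denat, 1.9, 0.9)
#> Two-state stability fit (8 points, fD window [0.02, 0.98]):
#>   dG0_water = 1.971 kcal/mol, m = 0.991 kcal/mol/M
#>   Cm = 1.99 M, K_Unf = 0.0359 (T = 298.15 K), R^2 = 0.9986

# pulse-chase turnover (true half-life 41 h, doubling time 20 h)
series <- simulate_growth_turnover(20, 41, noise_sd_rel = 0.02, seed = 11)
fit_turnover(series)
#> Turnover fit (25 points over 96 h):
#>   kd = 0.01685 1/h, t1/2 = 41.1 h (se 0.27), td = 20 h
```

The median pixel lifetime sits at the native 3.3 ns; the six detected
particles are the puncta whose drawn lifetimes exceed the 5 ns threshold
(two of the eight seeded puncta fall below it); the FCS fit recovers the
48 nm radius within noise; the stability and turnover fits recover their
generating parameters within their propagated uncertainties.

The end-to-end pipeline (scene → lifetimes → aggregates → curve fits),
with TIFF/CSV/JSON artifacts and a checksummed manifest:

```r
run_pipeline(default_config(seed = 1), "out/")
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/flimaggr`.

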