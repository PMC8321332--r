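# fustherm

Temperature monitoring for MR-guided focused ultrasound (MRgFUS), in R.

During a focused-ultrasound treatment the only noninvasive thermometer is
the MR scanner itself: the water proton resonance frequency (PRF) shifts
by about −0.01 ppm/°C, so the phase of a gradient-echo image accrued over
the echo time encodes the temperature change,

    Δφ = 2π · γ · α · 10⁻⁶ · B₀ · TE · ΔT.

`fustherm` is for medical-physics and image-analysis work on the safety
side of such treatments — asking whether unwanted heating (for instance
at the skin/gel interface, where signal is poor) would actually be seen
by the console. It implements:

* **Classical PRF-shift mapping** — wrap-safe baseline subtraction and
  phase-to-ΔT conversion (`classical_prf_map()`).
* **Referenceless thermometry** — the unheated background phase is
  estimated from an annulus of pixels around the focus and extrapolated
  underneath it, using a radial-basis-function network
  s(X) = p_m(X) + Σᵢ λᵢ φ(‖X − Xᵢ‖₂) with linear, thin-plate-spline,
  Gaussian or multiquadric kernels, or a weighted least-squares
  polynomial (`referenceless_map()`, `fit_rbf()`,
  `fit_polynomial_wls()`).
* **Rician-corrected SNR** — SNR = 0.655 · μ(object)/σ(background), with
  the 0.655 Rayleigh factor verifiable by Monte Carlo
  (`compute_snr()`, `rayleigh_noise_factor()`).
* **A synthetic phantom and sonication simulator** — a 105 mm
  tissue-mimicking phantom over skin and gel layers, 3 s frames, complex
  Gaussian noise, Gaussian hot spots driven by a 56-sonication schedule
  (20.0 ± 2.9 s heating, 85 s cooling, 2353 ± 611 J), optical-probe
  traces at 1 Hz — all seed-deterministic with stored ground truth
  (`gen_phantom_series()`, `gen_sonication_schedule()`,
  `gen_probe_timeseries()`).
* **A comparison pipeline** — per-sonication maximum rises, paired
  two-sided Wilcoxon signed-rank tests (exact by enumeration for n ≤ 12),
  and interpolation-error analysis of every referenceless method against
  the classical PRF reference (`run_study()`, `compare_methods()`,
  `wilcoxon_signed_rank()`).

## Worked example

Simulate a heated phantom, check the per-region SNR, reconstruct without
a baseline, and compare methods:

```r
library(fustherm)

cfg <- phantom_config()            # 105 mm phantom, 1 mm pixels, noise sd 1
sim <- gen_phantom_series(cfg, n_frames = 8,
                          hotspot = list(center_mm = c(56, 64), sigma_mm = 4,
                                         peak_deltaT = 16),
                          seed = 42)
sim$series
#> <image_series> 8 frame(s), 128x128 px, dt=3s, TE=0.01s, B0=1.5T

snr <- snr_over_series(sim$series, sim$rois)
aggregate(snr ~ region, data = snr, FUN = mean)
#>           region   snr
#> 1        gel_pad  2.22
#> 2        phantom 19.51
#> 3 skin_interface  3.08

referenceless_map(sim$series, 8, sim$rois,
                  interpolator = "thin_plate_spline", seed = 1)
#> <temperature_map> method=referenceless_rbf_thin_plate_spline frame=8 dT=[-4.31, 20.55] degC (797 valid px)

compare_methods(sim$series, sim$rois,
                methods = c("referenceless_rbf_linear", "referenceless_poly"),
                seed = 1)
#> <comparison_result> reference=classical_prf, 7 frame(s), alpha=0.05
#>                    method        bias       rmse statistic  p_value n degenerate
#>  referenceless_rbf_linear -0.07728551 0.54015395        12 0.812500 7      FALSE
#>        referenceless_poly  0.02086134 0.08713341        18 0.578125 7      FALSE
```

Reading the numbers: the phantom region has healthy SNR (~20) while the
skin interface and gel pad sit at 2–3, the regime where phase is mostly
noise. The hot spot is still ramping at frame 8 (the true peak there is
13.3 °C of the eventual 16 °C) and the referenceless map recovers the
heated region with per-pixel noise of a degree or two. Over the inner
ROI, both referenceless methods track the classical PRF reference with
sub-0.1 °C mean bias and non-significant paired differences (α = 0.05).

The full pipeline — probes, SNR, all kernels, figures, CSV/NIfTI/JSON
outputs — is one call:

```r
res <- run_study(out_dir = "study_out")         # ~15 s, seed-deterministic
```

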