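---
title: "Methods: PRF thermometry, referenceless phase baselines, and the synthetic phantom"
author: "fustherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRF thermometry, referenceless phase baselines, and the synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fustherm)
```

## The measurement model

During focused-ultrasound heating the water proton resonance frequency
drops approximately linearly with temperature. Over the echo time TE of a
gradient-echo acquisition this shift accrues as image phase, so the phase
difference between a heated and an unheated acquisition encodes the
temperature change:

$$\Delta\phi = 2\pi\,\gamma\,\alpha\,10^{-6}\,B_0\,TE\,\Delta T,$$

with $\gamma$ the gyromagnetic ratio (Hz/T), $\alpha$ the PRF thermal
coefficient (ppm/°C), and $B_0$ the field strength. `classical_prf_map()`
inverts this relation pixel by pixel using the wrap-safe principal-value
phase difference. Defaults are $\alpha = -0.01$ ppm/°C (the standard
aqueous-tissue coefficient; fat does not share it, which is why
thermometry in fatty layers is unreliable), $\gamma = 42.576\times 10^6$
Hz/T, $B_0 = 1.5$ T, and TE = 10 ms. With $\alpha < 0$, heating lowers the
phase and the conversion returns positive $\Delta T$. At these defaults
one degree corresponds to about 0.040 rad, so the principal value
saturates near $\pm 78$ °C; saturated pixels are counted and reported via
a warning, never silently unwrapped — no spatial or temporal unwrapping is
attempted anywhere in the package.

## Referenceless thermometry

Classical PRF mapping needs a baseline frame and therefore inherits every
inter-frame disturbance: motion, field drift, susceptibility changes.
The referenceless (self-referenced) alternative assumes the *background*
phase is smooth across the heated region. Two concentric regions are
drawn around the focus: an **inner ROI** containing all heating and an
**outer ROI** annulus that must remain unheated. A smooth surface is
fitted to the outer-ROI phase and extrapolated under the inner ROI; the
difference between measured and extrapolated phase then converts to
temperature exactly as above (`estimate_background_phase()`,
`referenceless_map()`). A spatially uniform drift term is absorbed into
the fitted surface, which is the method's practical appeal.

### The RBF interpolant

The fitted surface is a radial basis function network

$$s(X) = p_m(X) + \sum_{i=1}^{n} \lambda_i\,\varphi(\|X - X_i\|_2),$$

subject to the interpolation conditions $s(X_j) = f(X_j)$ and, when the
polynomial tail $p_m$ is present, the side conditions
$\sum_i \lambda_i q(X_i) = 0$ for every monomial $q$ of degree $\le m$.
Both are enforced by one symmetric saddle-point solve. Kernels and their
conventional pairings:

| kernel | $\varphi(r)$ | tail | node condition |
|---|---|---|---|
| linear | $r$ | degree 1 | not collinear/coplanar |
| thin-plate spline | $r^2\log r$ ($\varphi(0)=0$; $d = 2$) | degree 1 | not collinear |
| Gaussian | $e^{-(r/\rho)^2}$ | none | none |
| multiquadric | $\sqrt{r^2+\rho^2}$ | none | none |

`check_unisolvency()` decides the node condition by the numerical rank of
the monomial-basis matrix. The shape parameter $\rho$ defaults to the
mean nearest-neighbour distance among the retained centers, which keeps
the Gaussian/multiquadric kernel matrices away from the flat,
catastrophically ill-conditioned regime; condition estimates above
$10^{12}$ raise a warning, and outright singular systems are errors that
report the estimate.

Two choices deserve justification:

* **Center subsampling.** An outer annulus on a clinical matrix contains
  thousands of pixels; dense kernel solves scale cubically. `fit_rbf()`
  retains at most `max_nodes = 500` centers via a seeded uniform
  subsample. Fits are bit-reproducible per seed, and the interpolation
  conditions hold at the retained centers. Centers are fixed at
  (subsampled) data sites and only the output-layer weights are solved
  linearly; no iterative optimisation of center positions is performed.
* **The thermometry layer always attaches a degree-1 tail,** including to
  the Gaussian and multiquadric kernels whose classical pairing has no
  tail (and `fit_rbf()` keeps that default). Extrapolating across an
  excised hole must at minimum reproduce an affine background exactly;
  a bare multiquadric expansion reproduces affine data only approximately
  (we measured residual errors of order $2\times10^{-3}$ rad — several
  hundredths of a degree — on a noiseless affine phantom, versus machine
  precision with the tail). Interpolation coordinates are physical mm,
  so shape parameters are resolution independent.

The weighted least-squares polynomial (`fit_polynomial_wls()`) is the
classical low-order alternative; the study pipeline uses degree 2 by
default — degree 1 cannot represent the gentle curvature real background
phase exhibits, while degrees above 2 visibly chase noise on an annulus
whose width is a few pixels. A deliberately mismatched degree-1 fit on a
curved background is used in the tests to reproduce the known failure
mode where polynomial extrapolation overestimates the temperature.

## SNR estimation

Magnitude-image background noise is not Gaussian: with complex Gaussian
acquisition noise the pure-noise magnitude is Rayleigh distributed, with
standard deviation $\sqrt{2-\pi/2} \approx 0.6551$ times the
per-component $\sigma$. `compute_snr()` therefore reports

$$SNR = 0.655\,\frac{\mu(\mathrm{object})}{\sigma(\mathrm{background})},$$

which approximates the complex-domain SNR. `rayleigh_noise_factor()`
verifies the constant by seeded Monte Carlo. The standard-deviation
convention is population (divide by $N$) and is recorded in every report;
at ROI sizes of hundreds of pixels the distinction is far below the
estimator's sampling noise. A slab's "depths" are its slices; per-slab
aggregation, where wanted, is the mean across slices. The factor is
applied to the background noise only — no Rician bias correction of
object-region means is attempted, which matters only at object SNR of
order 1.

## What the synthetic phantom emulates — and what it does not

`gen_phantom_series()` builds a cylindrical tissue-mimicking phantom
(105 mm diameter) resting on a thin skin layer over a gel pad, imaged at
1 mm pixels on a 128×128 grid in 3 s frames, optionally as a stack of
slices forming a 16 mm slab. Signal amplitudes default to 20 (phantom),
3 (skin) and 2 (gel) against unit complex-noise sd, placing the phantom
near SNR 20 and the interface layers at SNR 2–4 — the low-signal regime
in which referenceless methods are known to break down, reproducible
here by construction. Background phase is affine (optionally quadratic)
in mm coordinates plus an optional linear temporal drift; heating is an
isotropic Gaussian hot spot whose amplitude follows exponential
saturation during the ~20 s sonication and exponential decay over the
85 s cooling interval. Schedules draw durations (20.0 ± 2.9 s) and
energies (2353 ± 611 J) from truncated-positive normals;
56 sonications is the default treatment length. Probe traces are
simulated at 1 Hz (the interferometric probes respond in under 1 s) with
a larger coupling gain for the probe under the treated-region centre.

The generator stores its full ground truth (background phase, per-frame
$\Delta T$ fields, envelope, noise sd), so recovery tests never need to
re-derive it. What it does **not** model: acoustic propagation and
attenuation, phased-array beamforming, bioheat diffusion (the Gaussian
hot spot with exponential dynamics is the minimal structure that
reproduces the observed heating/cooling curves qualitatively),
susceptibility artifacts, motion, and the fat-specific loss of PRF
sensitivity (skin is modeled only as a low-amplitude region). Passing
recovery tests on this phantom therefore demonstrates correctness of the
reconstruction pipeline, not robustness to every artifact of real
scanner data.

Inner/outer ROI defaults: the heated disc is taken as 3.5 hot-spot sigmas,
dilated by 2 pixels, and the outer annulus is 8 pixels wide. At 3.5σ the
Gaussian tail is $\sim 2\times10^{-3}$ of the peak, so outer-ROI
contamination from a 16 °C spot is a few hundredths of a degree — visible
in the strictest noiseless comparisons, negligible otherwise.

## The study pipeline

`run_study()` chains simulate → SNR → reconstruct (classical,
referenceless with linear/thin-plate/multiquadric kernels, polynomial) →
compare → report. Choices made where the design was open:

* **Pairing axis.** Method-vs-reference comparisons pair *per-frame
  inner-ROI mean* $\Delta T$ values. Pixels within a frame are strongly
  spatially correlated through the shared background fit, so treating
  them as independent pairs would overstate the test's sample size.
* **Wilcoxon conventions.** Zero differences are dropped before ranking;
  ties get mid-ranks. For $n \le 12$ retained pairs the null distribution
  is enumerated exactly over all $2^n$ sign assignments (ties included);
  beyond that a normal approximation with continuity and tie correction
  is used, and the method applied is recorded. Significance is fixed at
  $\alpha = 0.05$; raw p-values are reported with a count of tests
  performed, with no multiplicity correction.
* **Determinism.** Every stage seed derives from the configuration seed,
  and the summary JSON contains no timestamps, so identical seeds give
  byte-identical summaries. Stage timings go to the log only.

Default problem sizes — a 128×128 matrix, 36 frames (one sonication's
heating plus cooling at 3 s spacing), 500 RBF centers, a 56-sonication
probe arm at 1 Hz — complete a full study in well under a minute on one
core while keeping every estimator in its intended operating regime.

## Known limitations

* Phase is fitted as stored; if the *background* phase itself wraps
  within the fitted neighbourhood the smooth-surface assumption fails.
  Keep background coefficients (or the scanner's shim) such that the
  outer-ROI phase stays inside $(-\pi, \pi]$.
* The referenceless validity mask is the inner ROI only; no attempt is
  made to reconstruct temperatures in the outer ROI or beyond.
* File I/O is NIfTI (plus CSV/JSON/YAML sidecars); DICOM series must be
  converted upstream.
* `wilcoxon_signed_rank()` requires at least five nonzero differences;
  smaller studies report a degenerate test rather than a p-value.
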