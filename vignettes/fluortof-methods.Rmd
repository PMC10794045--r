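---
title: "Methods: time-of-flight fluorescence depth sensing in fluortof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-of-flight fluorescence depth sensing in fluortof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluortof)
```

## The measurement and its model

A gated single-photon camera synchronized to a picosecond pulsed laser
records, for every pixel, photon counts as a function of gate delay — a
time profile (TP). When the illuminated medium scatters light, the
returning pulse is delayed and broadened; when the return comes from a
fluorescent inclusion below the surface, it is additionally convolved
with the fluorophore's exponential decay and delayed in proportion to
the inclusion depth. `fluortof` models a TP as

\[
I(t) \;=\; \mathrm{IRF} \ast
\underbrace{\frac{A}{\sigma\sqrt{2\pi}}
e^{-(t-\Delta_\mathrm{tissue})^2/2\sigma^2}}_{\text{medium transfer}}
\;\bigl[\ast\, e^{-t/\tau},\ t\ge 0\bigr],
\]

with the bracketed factor present only for fluorescence. The model's
assumptions, in decreasing order of importance:

* **The medium transfer function is Gaussian.** A phenomenological
  choice: it fits measured reflectance profiles extremely well and keeps
  the model identifiable with three parameters.
* **Mono-exponential decay with known lifetime.** `tau` is an input
  (default 0.7 ns, typical of the red carbocyanine dyes this technique
  targets), measured externally; fitting it jointly with
  `delta_tissue` is ill-conditioned because both shift the pulse's
  centre of mass.
* **The IRF absorbs all setup-geometry delays.** Air-path delay, lens,
  and sensor timing enter through the measured IRF, so `delta_tissue`
  is a *relative* TOF. Comparisons across acquisitions require the
  reflectance-based time correction below.
* **Optical properties are laterally and axially uniform** within a
  calibration. The chain corrects for bulk scattering, not for
  stratified or heterogeneous media.

## Numerical implementation of the convolution

All computation is discrete on the instrument's gate grid (step `dt`,
default 17.857 ps; 1400 steps span 25 ns). Two choices matter:

* **The Gaussian × exponential product is evaluated analytically.** Its
  continuous convolution is the exponentially modified Gaussian (EMG),
  \(\tfrac{1}{2\tau}e^{\sigma^2/2\tau^2-(t-\Delta)/\tau}\,
  \mathrm{erfc}\!\bigl(\tfrac{\sigma/\tau-(t-\Delta)/\sigma}{\sqrt2}\bigr)\),
  which we sample on the grid (in log space, so neither factor
  overflows) and normalize to unit sum. Convolving the IRF with
  separately sampled Gaussian and exponential kernels instead would add
  a rectangle-rule error of order `dt/τ` (a few percent at the default
  gate step) concentrated at the pulse onset; the analytic kernel makes
  a delta-function IRF reproduce the EMG to machine precision, which the
  test suite exploits as an oracle.
* **Zero-padding to at least three axis lengths** before the FFT
  convolution, with the kernel laid out circularly over positive and
  negative lags, then cropping. Unit-sum kernels make the convolution
  photon-conserving (`sum(out) = A · sum(irf)`) up to the tail mass that
  genuinely leaves the recorded window.

Degenerate inputs are handled explicitly: `sigma < dt/2` warns (the
model is under-resolved on the grid), an IRF narrower than 3 gate steps
is an error, and profiles whose maximum estimate does not exceed the
tail baseline refuse to normalize.

## Profile processing

* **Normalization** maps a TP to [0, 1] using the mean of its `n_top`
  largest values (ties resolved toward earlier samples) and the mean of
  its last `n_tail` values. Defaults are 200 of 1400 samples,
  i.e. one-seventh of the axis; shorter axes scale accordingly. The
  top-window *mean* is 1 by construction, so a narrow pulse's single
  peak sample may exceed 1 — harmless, since the fit re-estimates `A`.
* **Smoothing** is a centred 35-sample moving average (625 ps at the
  default step) with shrinking symmetric windows at the edges, which
  avoids biasing the tails used for normalization. Fitting is done on
  *unsmoothed* profiles; smoothing serves display and threshold-timing.
* **Time correction across acquisitions.** The reflectance TP's rising
  edge, fitted linearly between 20% and 80% of the normalized pulse, is
  the acquisition's time reference; fluorescence TPs are shifted (linear
  interpolation for sub-sample shifts) by the difference of edge
  references. Shifts beyond a quarter of the axis span are rejected as
  implausible geometry changes.
* **Reflectance timing feature.** Normalized reflectance TPs are aligned
  on their **rising** edge and compared at 2% of the pulse maximum on
  the falling tail, where scattering-induced broadening accumulates.
  The alternative — aligning on the falling edge and thresholding the
  same edge — cancels the scattering shift and leaves only a saturating
  shape residual, which is useless for the linear calibration; both the
  alignment edge and both levels are exposed as parameters.

## Fitting

Bounded nonlinear least squares (Levenberg–Marquardt via `minpack.lm`),
with cost and step tolerances of 1e-8 and at most 500 iterations.
Bounds: `A > 0`, `sigma ∈ [dt/2, span/4]`, `delta_tissue` within a
quarter-span below zero and the span above. Initialization is data
driven: `delta` from the lag of peak cross-correlation with the IRF
(shifted left by `tau` for fluorescence), `sigma` from the excess FWHM
over the IRF's, `A` from the area ratio. The IRF profile is
baseline-corrected by its late-tail mean before entering the model —
dark counts are a constant floor, not part of the pulse the model
convolves. Fits report `R²`, convergence, and a `reliable` flag
(converged and `R² ≥ 0.5`); per-pixel map fits record failures in a
validity mask instead of aborting.

## The synthetic-data generator

The simulator exists so that every downstream stage is testable with
known ground truth. It emulates:

* the acquisition geometry (gate step 17.857 ps, 1400 gate positions,
  10.8 ns gate, 4 µs binary frames, 256 frames per gate sequence);
* photon statistics as `Binomial(F, 1 − exp(−λ/F))` per gate step —
  Poisson at low flux, pile-up saturation at high flux, hard-clamped at
  `F` (8-bit counts at the default 256 frames);
* per-pixel reproducible noise via counter-based stream seeds
  (`derive_seed`), so partial re-simulation is bit-stable;
* depth and scattering dependence of the fluorescence TP:
  `delta_tissue = k_fluo·z + c_fluo` with `k_fluo = k_corr·IL + c_corr`,
  dispersion `sigma(z) = sigma0 + s·μs′·z`, and surface amplitude
  attenuated by `exp(−2 μeff z)`.

Default constants (set once, from magnitudes typical of Intralipid
phantoms in the 635–660 nm band, and recorded as ground truth in every
simulated scan's provenance): `μs′ = 1.0·IL% + 0.05 mm⁻¹`,
`μa = 0.005 mm⁻¹`, `k_corr = 10 ps/mm per IL%`, `c_corr = 5 ps/mm`,
`c_fluo = 20 ps`, `sigma0 = 120 ps`, `s = 25 ps·mm⁻¹·mm`, reflectance
timing `30 + 6·μs′ ps` with width `60 + 10·μs′ ps`, IRF FWHM 110 ps
(the laser pulse is specified below 120 ps). The dispersion growth law
is deliberately explicit — the physical effect is observed but not
parameterized by theory here, so the simulator declares its own ground
truth rather than hiding it.

What the generator does **not** emulate: radiative transfer (no Monte
Carlo photon transport; the linear maps are phenomenological),
rolling-shutter row timing, laser jitter spectra, lateral light
spreading between pixels (each pixel's TP is independent), specular
reflections, and heterogeneous optical properties. Passing tests
therefore demonstrate that the *pipeline* inverts what the *model*
generates at realistic noise levels — not that the model captures every
property of real tissue.

## Calibration chain and inversion

All relations are ordinary least-squares lines. Per concentration,
`delta_tissue` is regressed on depth over the calibrated span (default
1–5 mm: the shallowest millimetre is excluded because its geometry is
not controlled reliably, and the signal reaches the noise floor near
5 mm); `c_fluo` — in principle a constant of the setup geometry — is
estimated as the mean of the per-concentration intercepts. The slope
table is regressed on IL to give `k_corr`, `c_corr`, and the medium
branch (reflectance timing or SFDI-derived `μs′`) on IL likewise. IL is
the chain's internal pivot: for media that are not Intralipid it is a
latent scattering index with no physical meaning of its own.

Inversion applies the guards explicitly: a non-positive reconstructed
slope flags the estimate invalid (with a reason) rather than raising,
and depths outside the calibrated span are flagged as extrapolation.
Depth is strictly increasing in `delta_tissue` whenever the slope is
positive.

Two typographic ambiguities in the attenuation equations are resolved
on physical grounds, with the alternative selectable: the attenuation
exponent is read as `exp(−2 μeff z)` (round-trip path `2z`), and
`μeff = sqrt(3 μa (μa + μs′))` (the diffusion-theory effective
attenuation, with the square root).

In the end-to-end study the *surface intensity* of a profile is its
smoothed pulse peak, not its time integral: the generator attenuates the
amplitude, while the integral also grows with scattering broadening,
which the attenuation law does not model.

## Mapping

`bin_scan` sums (never averages — photon statistics are preserved;
normalization later removes the scale) non-overlapping `f×f` blocks,
dropping partial trailing blocks, so the full 256×472 sensor area at
factor 8 yields 32×59 superpixels. `fit_map` runs the normalize-and-fit
pipeline per superpixel against the matching superpixel of the IRF scan.
Map post-processing uses an SNR-style intensity mask (default: 2
background standard deviations above the background mean) and Gaussian
smoothing by *normalized convolution* (values and validity indicator
convolved separately and divided), so masked holes neither leak values
nor bias their neighbourhood; default smoothing sigma is 1 superpixel.
`tof_to_topology` re-references the TOF map so its minimum valid value
is zero — the shortest inclusion-to-surface distance defines the surface
reference — and divides by the calibrated slope, giving relative depth.

## Study problem sizes

The test suite and `scripts/acceptance.R` run the same study code.
Parameter recovery uses 200 profiles on a 512-step axis with ground
truth `delta ∈ [0, 1500] ps`, `sigma ∈ [100, 600] ps`, and a peak
expectation of 600 counts (peak SNR ≈ 24 in the Poisson regime) — these
are ROI-accumulated counts, e.g. a 40×40-pixel region at well under one
count per pixel per frame sequence. The end-to-end study calibrates on
3 concentrations × 5 depths, with 20 000 peak counts at zero depth
(≈ 12 counts per pixel over a 40×40 ROI) decaying with depth
attenuation; reflectance features use five averaged replicates smoothed
with the 35-sample window, reflecting the acquisition protocol. The
two-cylinder phantom map runs 12×22 superpixels on a 256-step axis.

## Known limitations

* The reflectance-timing branch is intrinsically less accurate than the
  SFDI branch: the 2% crossing is a small, noise-sensitive feature, and
  convolution with the IRF makes it mildly nonlinear in the scattering
  level (total width grows as `sqrt(σ_r² + σ_IRF²)`). This matches its
  role as the quick, single-instrument alternative.
* `delta_tissue` trades off against an incorrect `tau`: an
  underestimated lifetime biases TOF upward (the test suite asserts the
  sign). Accurate lifetime input matters more than noise at high SNR.
* Depth estimates are only as good as the assumption of laterally
  uniform optical properties; the chain has no notion of depth-varying
  `μs′`.
* No spatial deconvolution: adjacent inclusions blur into each other
  through scattering, and the per-pixel model treats each superpixel
  independently.
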