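# fluortof

Depth sensing of fluorescent inclusions below the surface of turbid media
— tissue-like phantoms, resected tissue — from time-gated single-photon
imaging.

Fluorescence-guided surgery shows *where* a labelled lesion is, but not
*how deep* it lies. With a picosecond pulsed laser and a time-gated SPAD
(single-photon avalanche diode) camera, the arrival-time profile of the
returning fluorescence carries that depth: photons emitted deeper in a
scattering medium arrive later and more dispersed. `fluortof` implements
the computational side of this measurement end to end: simulation of
gated acquisitions with known ground truth, temporal-profile processing,
convolution-model fitting, depth calibration, and per-pixel depth
mapping.

## The model

A measured time profile (TP) is modelled as the convolution of the
instrument response function (IRF) with a Gaussian medium transfer
function and, for fluorescence, a mono-exponential decay:

```
reflectance:   I(t) = IRF * [ A / (σ√2π) · exp(−(t − Δtissue)² / 2σ²) ]
fluorescence:  I(t) = IRF * [ Gaussian(A, Δtissue, σ) ] * exp(−t / τ),  t ≥ 0
```

* `Δtissue` (ps) — mean of the Gaussian: the relative photon time of
  flight, the depth surrogate;
* `σ` (ps) — its standard deviation: temporal dispersion from scattering;
* `A` — amplitude; `τ` (ns) — fluorophore lifetime, fixed (default 0.7 ns),
  never fitted.

`A`, `Δtissue` and `σ` are estimated per profile by bounded nonlinear
least squares. The Gaussian × exponential product is evaluated in closed
form (an exponentially modified Gaussian) on the gate-step grid, so the
model is exact to the sampling.

Relative TOF maps to depth through a linear calibration chain pivoting on
the medium's scattering level (expressed as Intralipid concentration IL):

```
Δrefl = k_refl·IL + c_refl        (reflectance-timing branch)
μs′   = k_sfdi·IL + c_sfdi        (SFDI branch)
Δtissue = k_fluo·Depth + c_fluo,  with  k_fluo = k_corr·IL + c_corr
Depth = (Δtissue − c_fluo) / (k_corr·(feature − c)/k + c_corr)
```

and measured surface intensity is corrected for depth attenuation with
`L = I · exp(+2 μeff z)`, `μeff = sqrt(3 μa (μa + μs′))`.

## Worked example

Simulate a 16×16-pixel acquisition of a uniform inclusion 3 mm deep in a
2% Intralipid medium, extract the ROI-averaged profile, and fit it:

```r
library(fluortof)
ax    <- gate_axis(n_steps = 512)            # 512 gate steps of 17.857 ps
irf   <- make_irf(ax, pulse_fwhm = 110)
scene <- phantom_scene(matrix(3, 16, 16), il_percent = 2, peak_counts = 60)
scan  <- simulate_scan(scene, ax, sensor_response(), "fluorescence", seed = 42)
tp    <- extract_profile(scan, c(0, 0, 16, 16))
tpn   <- normalize_profile(tp, n_top = 73, n_tail = 73)
fit   <- fit_fluorescence(tpn, irf, tau = 0.7)
summary(fit)
#> Convolution-model fit (fluorescence)
#>   A            100.161
#>   delta_tissue 93.8017 ps
#>   sigma        279.137 ps
#>   tau (fixed)  0.7 ns
#>   R^2 = 0.99958; converged = TRUE; reliable = TRUE; iter = 7
```

The scene's ground truth is `Δtissue = 95 ps` (its TOF-depth slope of
25 ps/mm times 3 mm plus the 20 ps setup offset) and `σ = 273.75 ps`;
the fit recovers both to a few ps — well under the 17.857 ps gate step,
which is what sub-millimetre depth sensing requires. `depth_from_tof()`
(or `predict()` on a `build_chain()` calibration) then turns fitted TOF
into millimetres, and `bin_scan()` + `fit_map()` + `tof_to_topology()`
do the same per superpixel to produce depth maps.

A command-line wrapper is installed as `exec/fluortof` with subcommands
`simulate`, `fit`, `calibrate`, `depth`, `report` (see
`fluortof --show-defaults`).

## Scope and limitations

The simulator is a phenomenological generator (linear TOF-depth and
scattering maps, Gaussian IRF, binomial pile-up statistics), not a
radiative-transfer code; optical properties from structured-light (SFDI)
instruments are consumed as tables, not computed. See the methods
vignette (`vignettes/fluortof-methods.Rmd`) for the model's assumptions,
parameter defaults, and known limitations.
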