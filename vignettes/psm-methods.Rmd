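---
title: "Determining the EPID pixel-sensitivity map: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the EPID pixel-sensitivity map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A raw (non-flood-field-corrected) portal image factorises, up to a global
scale and noise, into two multiplicative fields on the pixel grid:

* the **pixel-sensitivity map (PSM)** — the imager's own per-pixel gain:
  what a perfectly uniform beam would record;
* the **beam-response** — the smooth off-axis shape of the incident beam as
  the detector sees it (flattened profile with exaggerated horns, small
  steering asymmetry, field-edge penumbra, a primary-collimator shadow in
  the corners).

The vendor flood-field calibration divides both out at once, which destroys
exactly the beam-shape information that linac and patient QA need. Replacing
the flood field by the PSM keeps the beam profile in the image. The package
implements four ways of estimating the PSM and a synthetic EPID/beam
simulator that provides the ground truth none of the methods has on a real
machine.

`epidpsm` follows the classic R modelling idiom: `fit_psm()` is the one
fitting front end, dispatching on the acquisition type and returning a
classed `psm_fit` with `print`, `summary`, `plot` and `residuals` methods
(`residuals()` returns the implied beam-response of a raw image).

## The simulator

`render_raw_image()` composes

```
pixels = MU * o * PSM(p) * BR(x(p), y(p)) * (SID_ref/SID)^2 + readout noise
```

where `o` is a per-irradiation output factor (mean 1), `x(p), y(p)` are the
pixel's beam-frame coordinates including the panel shift and SID
magnification, and all images live on the isocenter-projected grid. The
panel model (`panel_defect_model()`) freezes, per seed, a low-frequency
smooth gain field, a static per-pixel sensitivity spread, dead-pixel
columns and localized blob defects; readout noise is redrawn per frame.
This separation — static texture is a property of the panel, frame noise of
the acquisition — is what makes repeatability analysis meaningful.
Alternating beam/dark (ABDF) sequences additionally model a constant dark
offset, frame-to-frame lag, and a geometrically decaying residual from a
previous irradiation; discarding the leading pairs (40 of 100 by default)
removes the residual, which the tests verify. Single clinical images are
modelled dark-corrected (a beam frame minus a dark frame), as acquisition
systems deliver them; their readout noise is therefore `sqrt(2)` times the
per-frame value.

Working defaults and why:

* **Geometry** — 238 x 238 pixels spanning the clinical 40 cm active width
  (pitch 0.168 cm at isocenter). This keeps every end-to-end run at desk
  scale; the full 1190 x 1190 grid (0.034 cm pitch) is supported but not
  exercised by the test suite. All structural sizes below are stated at the
  238-pixel scale; physical sizes (cm) are unchanged by the downscaling.
* **Beam** — radial polynomial `1 + 2e-4 r^2 - 2e-6 r^3` with a Gaussian
  horn bump (amplitude 2.5%, radius 16 cm, width 4 cm), lateral tilt
  0.3%/10 cm (one-sided, matching the clinically acceptable <2% asymmetry a
  real beam shows on one side), penumbra scale 0.3 cm, and a radial corner
  shadow from 26 cm. The horn width matters: it must be broad enough that a
  5 cm sampling grid sees it, which is exactly the regime the shifted-field
  method is designed for.
* **Panel texture** — 3% smooth gain (10 cm correlation length), 2% static
  pixel spread, a ten-column dead band near -4 cm lateral (the clinical
  panel's dead columns, width scaled with the resolution), two blob
  defects.
* **Noise** — 0.05% output fluctuation per irradiation, 0.1% readout per
  frame, dark offset 10 counts, 2% lag.
* **Idealized transport image** (radial method) — per-pixel statistical
  noise 1%. A first-principles calculation at native resolution cannot
  reach even a few percent per 0.34 mm pixel; one desk-scale pixel
  aggregates a 5 x 5 block of native pixels, so ~5% native noise scales to
  ~1%.

What the simulator does **not** emulate: radiation transport, spectral or
energy dependence, imager-arm backscatter, sub-pixel panel-positioning
error, pixel-lag nonlinearity. Passing tests therefore show the estimation
machinery is correct under the stated noise model, not that any method is
validated on a physical imager.

## The four methods

**Shifted small field (`simulate_cmn_acquisition()` / `fit_psm`)** — a
constant 5 x 5 cm field imaged at 42 panel offsets (5 cm grid, lateral
-15..15, longitudinal -15..10 cm) plus a centered reference. The ratio of
offset to centered ROI means cancels the beam and yields the relative
sensitivity at each sampled point; dividing a wide-field image by these
gives beam-response samples; a tensor-product **not-a-knot cubic spline**
interpolates them and is continued linearly (boundary gradient) to the
panel edge; dividing the wide-field image by the fit gives the full PSM.
Numerical details that matter:

* ROI means use fractional (area-overlap) pixel weights so the 0.5 cm
  half-width ROI is exactly centred on its nominal point; with whole-pixel
  ROIs the block sits up to half a pixel off-centre, which biases each
  sample by the local beam gradient times that offset. The residual
  sub-pixel discretization limits beam cancellation to about 1e-4 at this
  pitch (exact in the continuum limit).
* The spline reproduces any bicubic surface exactly, so with a beam in that
  class recovery is limited only by ROI discretization (measured median
  |deviation| about 0.007% inside the sampled region). The Gaussian horn is
  not bicubic; 5 cm sampling leaves an interpolation residual of order
  0.05-0.1% near the horn ridge, and the linear extrapolation beyond the
  sample rectangle cannot follow the horn or the corner shadow — the
  method's documented edge weakness, asserted (not suppressed) by the
  tests.

**Small-shift propagation (`simulate_washu_acquisition()`)** — ABDF-averaged
37 x 37 cm fields at a centered reference plus one lateral and one
longitudinal shift of a whole number of pixels (shifts are refused
otherwise; no resampling). Two pixels that saw the same part of the beam
constrain their sensitivity ratio. The solver works in the log domain:
cumulative chains along each column (longitudinal shift), column offsets
tied by the lateral shift with the offset difference estimated as the mean
over all rows sharing the constraint (the geometric-mean merge of parallel
chains), and the remaining per-residue-class constants anchored on the seed
region's class means (central 20 x 20 px, overall mean 1).

The class constants deserve a note: with a shift step of `k` pixels the
constraint graph splits into `k^2` disconnected residue classes, and
nothing in the data ties them together — the anchoring is an assumption,
exact when the panel is flat across the seed region and accurate to
(texture SD)/sqrt(seed pixels per class) otherwise. The noiseless-exactness
scenario therefore uses a panel whose defects sit away from the centre, so
the machinery itself can be verified to machine precision; textured-panel
accuracy is covered by the noisy suite. A dead-pixel band wider than every
shift step genuinely disconnects the far side of same-parity chains; those
pixels are masked (`valid_mask` FALSE, neutral value 1), which reproduces
the known failure of this method class at dead pixels — the dead band shows
up in the implied beam-response instead of the PSM.

**Three-stage method (`simulate_varian_acquisition()`)** — stage 1 runs the
same propagation with a 50-pixel step on three full-field nets; its seed
region defaults to 1.5x the step (at least 9 seed pixels per residue
class — with fewer, the anchoring comb pattern is strong enough that its
alias under the two stage-2 magnifications is fitted as if it were a real
smooth error). Stage 2 takes two images at SIDs 115 and 175 cm, corrects
both by the current PSM with inverse-square scaling, resamples them
bilinearly onto a common beam-frame grid, and fits the residual smooth PSM
error as the exponential of a total-degree-4 polynomial (no constant term;
a global intercept absorbs the scale difference and is discarded). A
magnification-invariant error component would be unidentifiable, but every
non-constant monomial changes under the 115/175 rescaling, so the
polynomial is fully determined. Stage 3 acquires one 18 x 18 cm field at
four quadrant positions (48-pixel shifts), fits each image's log-ratio to
the four-image geometric mean with a degree-3 polynomial — the intercept is
kept here, because a quadrant-constant PSM error appears exactly as a
constant — and applies the surfaces with cosine feathering across the panel
axes. Each stage is checked to be non-degrading on its own internal RMS
objective. The residue-class anchoring noise of the 50-pixel chains is what
leaves per-pixel sensitivity partly uncharacterised, so the implied
beam-response of this method is visibly noisy — the signature the tests
assert.

**Radial averaging (`simulate_radial_acquisition()`)** — the idealized
symmetric image (transport-calculation stand-in: uniform panel, symmetric
beam component, heavy per-pixel noise) is averaged over concentric 0.5 cm
rings, the ring profile is fitted with a weighted smoothing spline
(`stats::smooth.spline`, ring pixel counts as weights, smoothing parameter
by generalized cross-validation — noisy inner rings average few pixels),
and the measured raw image is divided by the radial fit. Any beam
asymmetry is unrepresentable and leaks into the PSM as an x-antisymmetric
deviation — the method's idealization bias, demonstrated by a correlation
test between the deviation map and its mirrored negation over the in-field
disk (r < 18 cm; outside, the square field edge against the radial fit
dominates with large symmetric artifacts).

## Normalization and comparison conventions

Every PSM is renormalized to the mean of the central 10 x 10 pixel block;
every beam-response to its central-axis value, taken as the mean of the
central 2 x 2 pixels since the beam axis of an even grid falls between
pixels. Both are idempotent and scale invariant. Comparisons are per-pixel
percentage deviation maps with mean/median/SD/95th-percentile summaries
(sample SD, n-1 divisor) and fixed-width histograms; medians are the
preferred location statistic because edge and dead-pixel outliers skew the
mean. Repeatability is 100 x SD/mean per pixel over repeated
determinations, summarised by its 95th percentile ("95% of pixels
repeatable to within"). For the radial method the beam-response is
determined once and removed from successive raw images, so its
repeatability measures the stability of the raw image itself and serves as
the reference floor for the other methods. The analytic prediction for the
readout-noise-only p95 is `100 * sqrt(2) * readout_sd / signal` scaled by
`sqrt(chisq_{n-1}(0.95)/(n-1))` for the sampling spread of an n-repeat SD;
the measured value sits above it by the spatial spread of the signal map,
within the factor-of-1.5 the tests allow.

## Problem sizes and determinism

The test suite and the acceptance script run everything at the 238 x 238
scale: the noiseless exactness suite, one noisy run of each method (100
ABDF pairs per sequence where applicable), a three-repeat repeatability
set, and the oracle equivalences, a few minutes in total. Every stochastic
quantity is seeded: the panel texture by the defect-model seed, each
acquisition by an explicit seed, and scenario drivers fan one base seed out
with fixed strides so adding an acquisition never perturbs earlier ones.
Re-running any pipeline with the same seeds is bitwise reproducible.

## Known limitations

* The minimal two-shift plan cannot bridge dead bands wider than its step
  (masked, by design); richer shift patterns would, and the plan is
  configurable.
* Beam cancellation in the shifted-field method is exact only in the
  continuum; at 0.168 cm pitch the ROI discretization floor is ~1e-4.
* The spline beam-response fit is trusted outside the sampled rectangle
  only to first order (linear continuation); corner behaviour is
  deliberately left as the method exhibits it.
* The simulator's noise magnitudes are chosen to make method differences
  visible at desk scale, not calibrated to any particular linac.
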