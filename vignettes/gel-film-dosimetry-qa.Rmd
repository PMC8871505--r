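---
title: "Gel and film dosimetry QA for Gamma Knife single shots: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gel and film dosimetry QA for Gamma Knife single shots: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gkdosegel)
```

## What the package models

Stereotactic radiosurgery with a Leksell Gamma Knife delivers very high
doses through small collimators (4, 8 and 16 mm), so routine quality
assurance must verify both the delivered dose and the millimetre-scale
geometry of a shot. Two readout systems are modelled side by side:

* **nPAG polymer gel** read out by MRI. Radiation-induced polymerization
  raises the transverse relaxation rate R2 = 1/T2, so R2 acts as a dose
  surrogate. A dual-echo spin-echo acquisition (TE 89 and 145 ms) yields
  R2 per voxel by the two-point formula
  `R2 = ln(S(TE1)/S(TE2)) / (TE2 - TE1)`.
* **Radiochromic film** read on a flatbed scanner (1200 dpi). The film
  darkens with dose; the response variable is the net optical density
  `OD = log10(PV_unexposed / PV_exposed)`.

Both arms run end to end on synthetic data: a ground-truth dose field is
generated analytically, forward-modelled into MRI magnitude images or a
film scan, mapped back to dose through a fitted calibration curve, and the
result is compared against the truth by profile FWHM and by per-isodose
structural similarity (SSIM).

## The synthetic shot field

A single shot is modelled as a radially symmetric flat top convolved with
a Gaussian penumbra (error-function edges):

$$g(r) = \tfrac12\left[\operatorname{erf}\!\frac{a-r}{\sqrt2\,\sigma} +
\operatorname{erf}\!\frac{a+r}{\sqrt2\,\sigma}\right],$$

where the plateau half-width $a$ is solved numerically so the analytic
FWHM equals the collimator's planning-system reference width exactly
(6.2, 11.3 and 19.8 mm for 4, 8, 16 mm), and $\sigma$ defaults to
FWHM/6. The field is scaled so the center dose equals
`prescription_dose / prescription_isodose` — a 4 Gy@50% prescription puts
8 Gy at the center. Multiple shots superpose additively. Effective output
factors (0.814 / 0.90 / 1.00) enter only the beam-on-time bookkeeping:
they scale delivered dose through time, not the normalized field shape.

This shape is a modelling choice: it reproduces the flat-topped,
steep-edged single-shot profiles of planning-system exports and has an
analytic FWHM, but it ignores sector geometry and source attenuation, so
its tails are cleaner than a measured field's.

## Response models and their defaults

**Gel.** `R2(D) = R2_0 + s·R2_0·D_sat·(1 − e^{−D/D_sat})`, so the
*normalized* response `(R2 − R2_0)/R2_0` has low-dose slope `s` — the
quantity a gel calibration curve reports. Defaults: `s = 0.084` Gy⁻¹ (the
R2-based sensitivity the calibration experiments are built around),
`R2_0 = 8` s⁻¹. The zero-dose rate is a free parameter of the model — only
the normalized response is constrained by calibration data — and 8 s⁻¹
(T2 = 125 ms) places both echo times on the informative part of the decay.
`D_sat = 400` Gy makes the response depart from linearity by under 2.5%
across the calibrated range, consistent with a well-pronounced linear
response up to 10 Gy@50% with only a mild saturation tendency at the top
of the range. MRI magnitude noise is Rician: Gaussian noise of equal SD on
both complex channels.

**Film.** `OD(D) = OD_sat (1 − e^{−D/D_s})` with `OD_sat = 0.5`,
`D_s = 5` Gy, so the low-dose slope is `OD_sat/D_s = 0.100` Gy⁻¹ and
saturation is evident from about 4 Gy upward — markedly earlier than the
gel, which is the behaviour that drives the film arm's FWHM bias below.
Pixel value follows transmission, `PV = PV_0·10^{−OD}`, with additive
scanner noise clipped to the 16-bit range.

Dose bookkeeping uses the prescription convention throughout: "4 Gy@50%"
means 4 Gy at the 50% isodose and twice that at the center. Calibration
tables carry whichever dose axis the experiment used; the fit is agnostic
as long as the axis is consistent, and delivered doses can include a
scalar ionization-chamber correction (a fraction of a percent) applied by
the caller.

## Calibration fitting

`fit_dose_response()` is weighted least squares (weights 1/sd²; unweighted
when any sd is zero) over points within the linear range. When per-point
sds are supplied they are treated as known variances, so the slope SE
comes from `(XᵀWX)⁻¹` without a residual rescale; this keeps ±2·SE
intervals at their nominal coverage even with few calibration points. With
`linear_max_dose = "auto"` the bound is the largest candidate from
{4, 8, 10, 20, 40} Gy for which a lack-of-fit F-test of the line against a
saturating-exponential alternative is not significant at α = 0.05; if
every candidate shows lack of fit the smallest usable bound is kept. The
auto procedure is this module's own device — published practice typically
eyeballs linearity — and it needs at least four points below a candidate
to test it.

`invert_response()` is the linear inversion `(response − intercept)/slope`
with two flags: negative doses are clipped to zero (`clipped`) and doses
beyond the calibrated bound are returned but marked `saturated`. Dose maps
therefore never silently extrapolate the calibration.

## What the noise-free end-to-end run shows

With noise off, simulate → R2 map → normalize → calibrate → reconstruct
recovers the truth within 1% of Dmax inside the linear range; the residual
is the small curvature of the gel response against the straight-line
calibration, not numerics. The FWHM of the reconstructed 4 mm field is
within 0.1 mm of the generator nominal (the profile analyser interpolates
half-maximum crossings linearly between samples, so its intrinsic error
shrinks quadratically with spacing).

The film arm behaves differently by design: profile shots put 8 Gy at the
center while the film response saturates from ~4 Gy, so inverting with a
curve calibrated on its linear range compresses the peak and widens the
measured FWHM by roughly 13–15%. The QA report consequently shows the gel
passing the 5% FWHM deviation limit and the film failing it — mirroring
the experimental finding that film met the limit only in favourable cases,
though the physical mechanisms there (scanner optics, post-irradiation
darkening) are not the ones modelled here, and the measured film widths in
the published comparison are narrower than reference, not wider.

## Profile analysis and the deviation conventions

`fwhm()` takes the observed peak (leftmost sample on ties) as the
reference level — matching small-field practice on normalized profiles —
and interpolates the two half-maximum crossings linearly. A profile that
never falls below half-maximum on one side errors out rather than
guessing: that is a truncated field of view.

`fwhm_deviation()` makes the denominator explicit because the published
comparison table this package reproduces mixes conventions: its gel 8 mm
cell (4.2%) matches `|Δ|/measured`, while the film 4 mm cells (9.7%, 4.8%)
and gel 4 mm (3.2%) match `|Δ|/reference`, and no single convention
reproduces every cell. The QA report therefore prints both and takes the
pass/fail convention as a parameter (reference by default).

## Similarity scoring

Alignment is an exhaustive integer-pixel translation search maximizing
Pearson correlation over the overlap (at least 25% of the area), with
deterministic tie-breaking. This replaces the image-recognition matching a
clinical workflow might use: for rigid phantom geometry a correlation
search is exact, deterministic and dependency-free.

Segmentation computes a 3×3 Sobel edge magnitude (reflected boundaries)
and nested isodose bands at the requested levels (default
90/80/70/60/50/30/10% of Dmax); band 1 is the highest band and the bands
partition the map. "% of Dmax" uses a robust maximum — the mean of the
hottest 0.5% of valid voxels — which equals the literal maximum on clean
flat-topped fields but resists single-voxel noise spikes.

SSIM uses the standard Gaussian-window form (11×11 window, σ = 1.5,
C1 = (0.01 L)², C2 = (0.03 L)²) with the dynamic range L = 100 on percent
maps. Scores are means of the local SSIM map, globally and per band. The
"radiosurgical dose range" is operationalized as everything at or above
the 50% isodose; 10–50% is the radiotherapeutic range. The level split and
the SSIM constants are conventions of this package — standard published
defaults — since the comparison procedure itself fixes neither.

## Problem sizes and numerical choices

The shipped analyses use grids a desk machine handles in seconds: the QA
pipeline runs 13×81×81 voxels per shot (2.5 mm slices, 0.5 mm in-plane),
FWHM convergence checks refine down to 0.125 mm, film scans run at their
native 1200 dpi on a 24 mm region, and calibration recovery uses 200
replicates of six-cuvette experiments. Tie-breaks are deterministic
everywhere (leftmost peak sample, smallest-magnitude shift), all noise is
seeded per stage from one configured seed, and reports serialize with
fixed numeric formatting so identical configurations produce byte-identical
output bundles.

Degenerate inputs fail loudly rather than silently: shots outside the
grid, widths unresolvable at the grid spacing (FWHM < 2 spacings), equal
echo times, empty or fully invalid reference regions, constant images in
the alignment search, and profiles truncated above half-maximum all raise
errors. Low-signal voxels in R2 mapping are the one soft failure: they are
masked invalid (default floor: 3× a noise-SD estimate from robust first
differences) and propagate as invalid dose voxels, because a single dark
voxel should not kill a map.

## What passing tests do and do not show

The synthetic generator emulates the geometry and response behaviour the
study conditions describe: analytic single-shot fields at the planning
reference widths, mono-exponential dual-echo signal with Rician noise, and
saturating film response. It does not emulate B1/B0 inhomogeneity, slice
profiles, multi-echo stimulated echoes, gel diffusion or temporal
darkening, scanner lateral response, or positioning uncertainty. Passing
the suite therefore demonstrates that the analysis chain is correct and
self-consistent at realistic signal levels — not that a physical gel
experiment would achieve these numbers.
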