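---
title: "Methods: RGB colour-space indices and trial analysis in phenorgb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RGB colour-space indices and trial analysis in phenorgb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorgb)
```

## What the package computes

`phenorgb` turns plot-level canopy photographs from consumer RGB cameras
(ground shots or crops out of a UAV orthomosaic) into vegetation indices, and
carries those indices through a standard low-input field-trial analysis:
correlations against grain yield, quartile yield groups and their overlap
across treatments, and stepwise multiple regression models of yield.

The chain is: 8-bit RGB image → colour planes (HSI hue/saturation/intensity,
CIELab `L a* b*`, CIELuv `L u* v*`) → one index record per plot → trial-level
statistics.

## Colour model and its assumptions

All CIE conversions assume the image is sRGB-encoded (IEC 61966-2-1) with a
D65 reference white, the default JPEG output of the consumer cameras this
workflow targets. No ICC profiles, chromatic adaptation or radiometric
calibration are applied: the calibration-check module exists precisely to
verify that a camera is close enough to nominal that correction is
unnecessary, and correcting by a single chart photo frequently *hurts*
index-yield correlations, so linear correction is opt-in
(`apply_color_correction()`) and never implicit.

Hue and saturation come from the hexcone model (`grDevices::rgb2hsv`), the
same family of hue used by ImageJ/Java image tooling: red at 0°, green at
120°, blue at 240°. Achromatic pixels (saturation exactly 0) have no defined
hue; they carry an explicit invalid flag, count in index denominators as
scene pixels, and can never count as green. "Intensity" is `mean(R,G,B)/255`
and is reported separately from CIELab lightness `L`, since the two respond
differently to exposure and are both useful summaries.

The vectorized conversion path is verified in the test suite against an
independently coded scalar per-pixel implementation of the same CIE formulas
(agreement to 1e-6 on random pixels) and, more loosely, against
`grDevices::convertColor`, which uses slightly different matrix precision.

## The indices

* **GA** (green area): fraction of pixels with hue in `[60°, 180°)` — yellow
  through bluish green. A vegetation-cover proxy.
* **GGA** (greener green area): the restrictive range `[80°, 180°)`,
  excluding yellowish-green tones of stressed or senescing tissue.
* **CSI**: `100 (GA − GGA) / GA`, the yellowish share of the detected
  canopy. When `GA = 0` there is no canopy to assess, so CSI is missing
  rather than 0 — `0/0` is not "no senescence".
* **TGI**: `−0.5 [190 (R_red − R_green) − 120 (R_red − R_blue)]` with
  channel means divided by 255 standing in for broadband reflectance at
  670/550/480 nm. The coefficients 190 and 120 are the wavelength
  differences `λ1 − λ3` and `λ1 − λ2`; `tgi_coefficients()` exposes the
  expansion for any band centres.
* **NGRDI**: `(G − R)/(G + R)` on channel means; missing for an all-black
  image.
* **NDLab / NDLuv**: `((1 − a*) − b*)/((1 − a*) + b*) + 1` and the same on
  `u*`, `v*`. The complement of `a*` (or `u*`) makes greener canopies push
  the index up the way near-infrared pushes NDVI up, while yellowing pushes
  it down.

Hue intervals are closed on the left and open on the right; the choice is a
measure-zero convention but makes threshold behaviour deterministic.

### Numerical behaviour of NDLab/NDLuv

The normalized-difference formula is implemented literally, and two of its
properties deserve attention. At the chroma origin (`a* = b* = 0`) it
evaluates to 2, outside the nominal `[−1, 1]` band of a normalized
difference. More importantly the denominator `(1 − a*) + b*` (or
`(1 − u*) + v*`) can change sign: saturated red-brown soil often has
`u* > v* + 1`, so per-pixel NDLuv values near the sign change are unbounded
in either direction. Both quirks are deliberate — the package computes the
published formula rather than a privately "fixed" variant — but they mean
NDLuv plot means over strongly coloured soil backgrounds should be
interpreted with care. Per-pixel evaluation excludes pixels whose
denominator is within `eps = 1e-6` of zero and is the default (matching how
GA/GGA are defined per pixel); evaluation on the plot-mean `a*`/`b*` is
available via `per_pixel = FALSE` for sensitivity analysis. The test suite
checks the greener-scene ordering of NDLuv on a low-chroma soil background
for exactly this reason.

## Plot segmentation

ROIs are axis-aligned rectangles in a CSV (`plot_id, x0, y0, x1, y1`,
0-based, half-open), the minimal faithful format for plot cropping; polygon
masks would be a natural extension. Cropping is pixel-exact, so
"crop then index" equals "index the pre-cropped image" identically, and
`batch_index()` records per-plot failures without aborting a run.

## Camera QA

`color_check()` regresses measured chip values on the 24-chip reference per
channel (R, G, B, L, a\*, b\*) and flags channels with `R² < 0.80`. Chip
colours are measured as the per-channel **median** over the chip ROI, which
is robust to specular pixels. The packaged reference
(`inst/extdata/colorchecker_reference.csv`) holds the widely published
nominal sRGB values of the classic 24-patch chart with Lab columns derived
from them under D65; because the regression is invariant to affine
re-specification of the reference, any published edition can be substituted.

`vignetting_transects()` extracts the central row and column of the R, G, B,
hue, a\* and b\* planes, keeping only sunlit-soil pixels: hue outside
`[60°, 180°)`, saturation above 0.1 and intensity above 0.2 (the complement
of the vegetation hue range, minus shadow; all configurable — the filter
range is a package choice since no numeric range is standard). Lens falloff
appears as a dip of the RGB transects toward the edges, while the
lightness-separated a\*/b\* transects stay comparatively flat; on synthetic
cos⁴-distorted soil scenes the chromatic transect variance is more than an
order of magnitude below the RGB variance, which is the testable form of the
claim that CIELab/CIELuv indices are robust to vignetting and variable
illumination.

## Agronomy and trial statistics

Grain yield is `X × 10 / area` in Mg/ha with the 5.25 m² default harvested
area (2 rows × 0.75 m × 3.5 m). The yield loss index
`GYLI = (GY_OP − GY_LOW)/GY_OP × 100` uses genotype means per treatment;
genotype yield is the replicate mean before quartiling (per-genotype
box-plot style summaries imply replicate aggregation, and no other
aggregation is stated anywhere). Quartile groups are rank-based, descending,
with ties broken by genotype name so labelling is invariant to row order.
`group_overlap()` reports, per group, the percentage of its genotypes that
keep the group under the second labelling, rounded to integer percent.
Moisture standardization of grain weight is assumed upstream. ASI is
`SD − AD` with negative values retained.

Fisher-LSD letters are computed from the pooled ANOVA mean square: pairwise
differences are compared against
`t_{1−α/2, dfe} · sqrt(MSE (1/n_i + 1/n_j))`, and letters are assigned by
merging maximal runs of mutually non-different groups over the mean-ordered
list (exact for the balanced designs used here).

Stepwise models use `MASS::stepAIC` (penalty `k = 2`) over a named predictor
menu on complete cases, forward, backward or both. `simplify_model()`
implements the reported-model reduction rule: repeatedly drop predictors
with `p ≥ α`, and among predictor pairs correlated beyond `|r| ≥ 0.7`
(configurable; no standard numeric threshold exists for "auto-correlation
detected") keep the one with the stronger marginal correlation to yield,
refitting after each drop. Because predictors are only ever removed, the
simplified R² can never exceed the full model's — a property the tests
assert on every simulated fit.

## What the synthetic generator emulates — and what it does not

`render_scene()` builds canopy images from three pixel classes — soil
background, green vegetation, chlorotic (yellow-green) vegetation — placed
as seeded elliptical Gaussian blobs so that cover is spatially coherent, the
way real canopies are, rather than salt-and-pepper noise. The class field is
thresholded at its empirical quantile, so programmed fractions are hit to
1/N exactly. Class colours are base RGB triplets (defaults: sunlit
red-brown soil (130, 90, 60), green canopy (70, 150, 60), chlorotic tissue
(140, 160, 40)) plus truncated Gaussian jitter clamped at ±2σ; the clamp is
what lets the generator *guarantee* that chlorotic pixels stay inside the
narrow `[60°, 80°)` hue band and green pixels inside `[80°, 180°)`, so mask
counts are an exact oracle for GA/GGA. Vignetting is applied
multiplicatively in linear RGB (falloff physically acts on sensor
irradiance) as `cos(θ)⁴` with the corner attenuated to `1 − strength`.

`simulate_trial()` draws genotype yield effects from a bivariate normal
across the LOW/OP treatments (defaults 2.93 ± 0.58 and 9.62 ± 1.24 Mg/ha,
cross-treatment correlation 0.55, chosen so simulated trials sit in the
reported range of a 64-genotype low-N maize trial, with genotype spans near
1.5–4.4 and 6.7–12.3 Mg/ha), plus small plot residuals. Under LOW, anthesis
date and ASI are linked negatively to the genotype yield effect and
senescence rises as yield falls; under OP the phenology links are switched
off — the sign structure that makes agronomic covariates and image indices
complementary in multivariate models. All generative coefficients are
returned so recovery tests compare estimates against truth.

What the generator does **not** emulate: real soil texture and residue,
specular leaves, mixed pixels at leaf edges, shadows cast by the canopy,
perspective, atmospheric effects, or mosaicking seams. Passing tests
therefore demonstrate that the algorithms are implemented correctly against
known ground truth, not that field correlations of any particular magnitude
will be observed on real imagery.

## Problem sizes and numerical choices

The test and acceptance workloads use deliberately compact problem sizes
chosen as sufficient for their purpose: 80 × 60 px scenes for fraction
recovery (quantile thresholding makes recovery exact at any size),
301 × 201 px for vignetting transects (odd dimensions put a pixel exactly
on the optical centre), 192 observations — one full trial's plot count —
for the selection-consistency and null simulations, and 100 seeds for
Monte-Carlo rates. The NDLab/NDLuv denominator guard is `1e-6`; quartile
ties break by genotype name; hue means are circular (mean resultant
vector), never arithmetic, because plot hue distributions can straddle the
0°/360° wrap.

## Known limitations

* Rectangular ROIs only; no automatic plot detection or georeferencing.
* No NIR band exists in RGB input, so NDVI is an input column (from a field
  sensor), never computed.
* The literal NDLab/NDLuv formulas are unstable over saturated red-brown
  soil (see above).
* Fisher LSD is unprotected (letters are computed whether or not the
  omnibus F test rejects); protect by checking the reported ANOVA p-value
  first if desired.
* Moisture correction of grain weight and radiometric reflectance
  calibration are out of scope.
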