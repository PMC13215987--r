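---
title: "Automated single-slice abdominal adipose tissue quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated single-slice abdominal adipose tissue quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicefat)
```

## The problem

Visceral adipose tissue (VAT) — fat surrounding the abdominal organs — is a
stronger cardiometabolic risk marker than total adiposity, but separating it
from subcutaneous adipose tissue (SAT, the peripheral fat ring under the
skin) normally requires manual tracing on cross-sectional imaging. On a
single axial T1-weighted abdominal MRI slice, fat is hyperintense and
opposed-phase acquisition sharpens fat/lean interfaces, so classical
intensity-based segmentation is viable. `slicefat` implements a fully
automated pipeline for this setting:

1. **Preprocess** the slice (adaptive Wiener denoising, top-hat/bottom-hat
   contrast enhancement).
2. **Segment** adipose vs. everything else with one of three interchangeable
   backends: Otsu thresholding, k-means, fuzzy c-means (FCM).
3. **Remove arms** with an abdominal mask (auto-constructed or supplied).
4. **Delineate VAT from SAT** by comparing centroid-to-image-center
   distances of the largest connected adipose regions.
5. **Quantify** masks as physical areas (cm²), distribution indices, and
   multi-slice volumes.
6. **Evaluate** against reference masks (confusion matrix, Dice, Hausdorff).
7. **Calibrate** the systematic underestimation of threshold-derived areas
   with weighted-least-squares regression, with full diagnostics and
   internal validation.

No patient data ship with the package. A parametric phantom generator
produces synthetic slices with exact ground truth, and a cohort simulator
produces tables with the statistical structure of the calibration models,
so every stage is testable end to end.

## Coordinate and intensity conventions

Images are numeric matrices indexed `[row, col]`, row 1 at the top, with
intensities on `[0, 1]` (8-bit files are divided by 255; 16-bit input is
rescaled). Centroids and the image center `((rows + 1)/2, (cols + 1)/2)`
use the same 1-based convention. Masks are integer 0/1 matrices; on disk
they are 8-bit rasters with levels 0/255. Multi-channel input is collapsed
by the fixed luminance weights 0.299/0.587/0.114 with a warning.

## Preprocessing

The adaptive Wiener filter computes, in a local window (default 6×6, even
windows extend one pixel further toward larger indices), the mean $m$ and
variance $v$ of the image and returns
$m + \frac{\max(v - \nu, 0)}{\max(v, \nu)} (x - m)$, where the noise
variance $\nu$ defaults to the mean of all local variances. Flat regions
collapse to their mean; edges are preserved. Borders use reflect padding,
which avoids the dark-frame artifacts that replicate-with-zeros schemes
seed into later thresholding.

Contrast enhancement combines morphological top-hat (image minus opening)
and bottom-hat (closing minus image) responses as

$$\mathrm{enhanced} = \mathrm{clip}(\,x + \mathrm{tophat}(x) -
\mathrm{bothat}(x),\ [0,1]\,).$$

This is the classical formulation for "combine the hat transforms with the
image": bright structure smaller than the structuring element is amplified,
dark detail suppressed, widening the adipose–lean separation. The
structuring element is a disc of radius 5 px by default — on the order of
the SAT ring thickness at typical export resolution — configurable in shape
(`disc`/`square`) and radius. Equal unit weights are used for the two hat
terms; the weighting is deliberately not exposed as a tuning surface
because no principled value other than 1 exists for this pipeline.

## Segmentation backends

All three backends operate on the flattened intensities. Internally the
pixels are collapsed to weighted unique values, which is mathematically
identical and much faster for near-discrete intensity histograms.

* **Otsu**: 256-bin histogram over the data range; the threshold maximizes
  between-class variance; ties resolve to the lowest maximizing cut; the
  mask is `intensity > threshold`. Constant images are a degenerate-input
  error, not an empty mask.
* **k-means** (`k = 2`): Lloyd iterations from k-means++-style seeding,
  deterministic given the seed. Five restarts are run and the lowest
  within-cluster SSE kept: single-start Lloyd on a trimodal
  background/lean/fat histogram converges to the wrong local optimum
  (background vs. everything) in a nontrivial fraction of seedings, and the
  restart remedy is standard. An emptied cluster is re-seeded at the sample
  farthest from all centers, never silently dropped.
* **FCM**: standard alternating updates
  $u_{ij} = 1/\sum_k (d_{ij}/d_{ik})^{2/(m-1)}$ and centers as
  $u^m$-weighted means, fuzziness $m = 2$, tolerance $10^{-5}$, cap 300
  iterations. A pixel coinciding exactly with a center takes membership 1
  there (no division by zero). The hard mask assigns maximum membership.

In every backend the adipose class is the cluster/side with the higher
center — fat is hyperintense — never a label index, which would be
arbitrary under random initialization. The k-means SSE and the FCM
objective are non-increasing per iteration; the test suite asserts both on
recorded traces, and checks FCM centers against an independent
implementation (`e1071::cmeans`).

## Arm removal and VAT/SAT delineation

Upper-extremity subcutaneous fat must not contaminate SAT. The abdominal
mask is constructed automatically: Otsu on the *raw* image yields the
bright body foreground (dominated by the SAT ring), morphological closing
(disc, radius 10 px) consolidates it, holes are filled, and the 8-connected
component containing the pixel nearest the image center is kept. Filling
holes *before* selecting the component matters: the foreground is an
annulus whose filled interior contains the center; selecting first would
pick whatever small central fat island happens to be nearest. A manually
drawn mask can always be supplied instead and is used verbatim.

Delineation labels the 8-connected components of the arm-free adipose mask
and compares the two largest by the Euclidean distance of their centroids
from the image center: the farther becomes SAT (the peripheral ring), the
nearer VAT; every smaller region is also VAT, the fragmented compartment.
Two degenerate cases warn rather than fail silently: a single region (SAT
with empty VAT — the signature of SAT–VAT bridging) and a centroid-distance
tie within $10^{-9}$ px (resolved by area). Pixel conservation holds by
construction: SAT ∪ VAT equals the delineated input.

The rule presumes the SAT centroid is measurably off-center (supine
posterior SAT is thicker) while the dominant visceral component is central.
Both presumptions are encoded in the phantom defaults below; on a perfectly
symmetric ring the rule would degenerate to the tie branch.

## Quantification

Pixel area derives from the field of view over the pixel grid *the masks
live on*: `(fov_row/n_rows)·(fov_col/n_cols)/100` cm². When the export grid
differs from the acquisition matrix (e.g. 2× interpolated exports), the FOV
must be divided by the export grid — that choice conserves total area
across the interpolation, which is the physically meaningful constraint.
Geometry is a required per-case input; it is never defaulted from file
headers. Distribution indices are VAT/TAT (%) and the VAT/SAT ratio, with
zero-denominator cases carried as `NA`, never infinity. Multi-slice series
aggregate as $V = (t + h)\sum_i A_i$ with slice thickness $t$ and
inter-slice gap $h$ (cm): each slice's area is extruded over its thickness
plus its share of the gap; the corresponding "thickness-plus-gap" product
is the only dimensionally consistent reading of the usual shorthand for
this estimator.

## Evaluation metrics

Pixel confusion counts define Dice $= 2TP/(2TP + FP + FN)$, the primary
accuracy metric under class imbalance. Two empty masks score Dice 1, one
empty scores 0 (documented conventions). The Hausdorff distance is the
symmetrized max-min Euclidean distance over the *full* foreground point
sets, in pixel units, computed via exact distance transforms; a
95th-percentile variant is available behind an argument. Reports re-derive
Dice from the stored confusion counts so the two can never disagree.

## Calibration of systematic underestimation

Threshold-based segmentation under-estimates adipose areas (partial-volume
pixels at compartment boundaries fall below threshold). The package ships
the published corrections as data files and as closed forms:

$$\mathrm{VAT} = 7.224 + 1.112\,\mathrm{VAT}_{\mathrm{Otsu}} +
7.583\,I_{\mathrm{obesity}} \quad (\mathrm{cm}^2)$$
$$\mathrm{SAT} = 0.67 + 1.037\,\mathrm{SAT}_{\mathrm{Otsu}} +
3.337\,I_{\mathrm{adult}} \quad (\mathrm{cm}^2)$$

These are cohort- and protocol-specific; the machinery to refit them is the
point. `fit_wls()` fits weighted least squares with inverse-frequency
Sex × Age weights (each demographic cell contributes equally regardless of
cohort imbalance; reference levels are female/child/normal-weight).
`select_model()` replaces stepwise selection with exhaustive subset
enumeration over the dummy-coded demographic main effects and their
interactions with the area predictor, always retaining intercept and area.
The default score is **BIC**, ties to fewer terms: BIC's consistency
(asymptotically selecting exactly the active set) fits the goal of a small
interpretable correction model, whereas AIC's fixed penalty of 2 admits
each inactive term with probability ≈ 16% even at large *n*. AIC remains
available. Diagnostics include per-term VIFs (optionally mean-centering
binary dummies before interaction products are formed — note that when the
partner main effect is in the model this is a pure reparameterization and
leaves that dummy's VIF unchanged), Bland–Altman limits of agreement
(mean ± 1.96 SD of paired differences, multiplier configurable), and BCa
bootstrap confidence intervals (bias correction from the bootstrap
distribution, acceleration from jackknife skewness; deterministic given a
seed). Internal validation offers leave-one-out and repeated k-fold
cross-validation with weights recomputed inside every training fold —
recomputing them on the full data would leak the held-out cases'
demographics into the fit.

## The phantom generator

`generate_slice_phantom()` renders, on a 176 × 256 grid (the ≈1.45 aspect
ratio of axial abdominal exports at half of a typical 352 × 512 export):

* an elliptical body (semi-axes 60 × 72 px) of lean tissue,
* a SAT ring with per-quadrant thickness, default (8, 10, 16, 10) px —
  posterior thickest, so the ring centroid sits ~7 px off-center,
* VAT as one dominant mass at the body center plus smaller satellite blobs
  within 60% of the lean interior radius, all mutually 8-disconnected by
  construction (rejection sampling with enforced gaps, bounded attempts),
* optionally two fat-rimmed arm ellipses in the lateral background with
  enough clearance that a disc-10 closing cannot bridge them to the body,
* intensity levels fat 0.85 > lean 0.35 > background 0.05, additive
  Gaussian noise clipped to `[0, 1]` (Rician available as an option).

The generator is a pure function of (spec, seed). With zero noise and no
arms the image takes exactly the three configured levels, and ground-truth
SAT/VAT/arm/background partition the pixels.

**What the phantom does and does not emulate.** It reproduces the
*geometry* the pipeline's decisions depend on — bright peripheral ring,
fragmented central fat, lateral arms, asymmetry — and a simple noise model.
It does not simulate MR physics: no bias field, no chemical-shift or
India-ink boundary artifacts, no partial-volume gradients, no intensity
non-uniformity across the FOV. Consequently, passing phantom suites
demonstrates the correctness of the algorithms under their stated
assumptions, not clinical-grade accuracy; the calibration module exists
precisely because real slices violate those assumptions in a systematic,
correctable way.

The cohort simulator draws the automated-area predictor uniformly over a
configurable range (default 20–300 cm²), assigns sex/age/obesity strata by
deterministic rounded fractions, and generates responses from the linear
model plus Gaussian residuals; zero residual SD gives exact responses, the
closed-form limit the coefficient-recovery tests rely on.

## Numerical choices and degenerate inputs

* Otsu: lowest maximizing threshold on ties; constant image → error naming
  the value.
* k-means: empty cluster → re-seed at farthest sample (logged);
  determinism from a single seed governing seeding and restarts.
* FCM: exact-coincidence membership convention; memberships sum to 1
  within 1e-12 (asserted).
* Delineation: single region and distance ties warn; empty mask errors.
* Hausdorff: undefined (error) when either mask is empty; Dice conventions
  for empty masks as above.
* Ratios with zero denominators are `NA`, never `Inf`.
* Bland–Altman needs n ≥ 2; BCa needs n ≥ 10 and returns a zero-width
  interval with a warning for degenerate statistics.
* Rank-deficient designs error at fit time naming the collinear terms;
  rank-deficient CV training folds are skipped, warned about, and counted.

## Problem sizes in the test suite

The shipped tests exercise 50-phantom batches per backend at the default
176 × 256 grid, 100-image oracle sweeps for Otsu/Dice/Hausdorff, 200-repeat
bootstrap coverage simulations at n = 200 with 10,000 resamples, and
selection/cross-validation simulations at n = 68 (the calibration cohort
scale) and n = 2000 (the selection-consistency check). These sizes were
chosen to give the stochastic assertions comfortable margins at desk scale.

## Known limitations

* The delineation rule assumes an intact SAT ring; a ring split into
  several arcs (surgical scars, extreme FOV cropping) is flagged by the
  single-region/tie warnings but not resolved.
* Two clusters only; mixed or intermediate tissues are forced to one side
  of the adipose boundary.
* The shipped correction equations transfer only to acquisitions matching
  their source protocol; refit on local data before quantitative use.
* No DICOM support: the pipeline expects exported TIFF/PNG rasters with
  geometry supplied explicitly.
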