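---
title: "Counting colonies and fitting their size distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting colonies and fitting their size distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonysizer)
```

## Background

The clonogenic survival assay scores the fraction of cells that retain the
ability to found a colony after a treatment such as irradiation. Plates are
fixed and stained (typically Giemsa, a purple-blue stain), scanned, and the
colonies counted. Counting by eye is slow and biased, and it discards a
second, biologically informative quantity: the *size* of each colony, which
reflects the growth rate of the surviving clone. Treatments can reduce the
colony count and, independently, shift the whole colony-size distribution
towards smaller colonies.

`colonysizer` implements both halves of that analysis as one package:

1. an image pipeline that counts stained colonies on a scanned round dish
   and exports every colony's area, and
2. a distribution module that bins the exported areas and fits Weibull and
   Gaussian models by nonlinear least squares, reporting the fitted mean
   colony size and its spread.

A synthetic plate generator with exact ground truth (colony centres, radii
and areas) makes every stage testable without any scanned data.

## The counting pipeline

`process_plate()` chains the following stages. All tunables live in a
single `pipeline_params()` object; once chosen for a batch they are frozen
and applied identically to every image, so residual counting bias
propagates equally across experimental arms instead of distorting their
comparison.

**Channel selection.** The RGB scan is split into channels and the channel
with the largest intensity standard deviation — the one in which colonies
contrast most with the dish — is kept (`select_channel()`). For purple-blue
stained colonies on a light dish this is typically green. Ties break in
fixed R, G, B order so the choice is deterministic. An alternative rule
(lowest mean intensity) exists in the literature for dark-stained objects on
light backgrounds; it can disagree with the standard-deviation rule on
adversarial images and is intentionally not implemented — the
standard-deviation rule is the one this pipeline commits to.

**Polarity.** Raw scans show dark colonies on a light dish; every later
stage assumes the opposite. `normalize_polarity()` inverts the channel when
the modal intensity (the background) lies in the upper half of the 8-bit
range, establishing a single "colonies bright" convention everywhere.

**Gaussian blur.** `gaussian_blur()` smooths sensor noise and homogenises
colony interiors so thresholding and watershed behave stably. Its standard
deviation `sigma` (pixels) defaults to a resolution-calibrated polynomial
(`default_sigma()`):

    sigma = 1.9e-6 * dpi^2 + 6.3e-4 * dpi + 1.3

Too large a `sigma` enlarges and fades colonies; too small a value leaves
noise that shows up later as spurious detections. The blur is a separable
convolution with a unit-mass kernel truncated at 3.5 sigma and
symmetric-reflection borders, which conserves the total image intensity to
floating-point accuracy (checked by a property test). `default_sigma()`
accepts `dpi = 0` as the limiting case and returns the polynomial's
constant term 1.3.

**Rolling-ball background subtraction.** Illumination gradients and
staining haze vary smoothly across a dish. `subtract_background()` models
that background as the envelope of a ball rolled under the intensity
surface — computed as a grayscale morphological opening with a disc-shaped
structuring element — and subtracts it, clipping at zero. The ball radius
defaults to `0.025 * dpi` px (`default_rolling_radius()`, rounded half-up,
floored at 1 px) and must be at least as large as the largest colony
diameter: an under-sized ball absorbs colonies into the background
estimate and erases them, a failure mode the test suite demonstrates on an
oversized disc.

**Thresholding.** `binarize()` sets pixels strictly above the threshold to
foreground. With `threshold = "auto"` the cut comes from the iterative
intermeans (IsoData) method; Otsu's method is available as an alternative.
Two numerical choices matter here:

* the automatic threshold is computed from *dish-interior pixels only*
  (inside the region of interest). Rim remnants and the scanner bed
  otherwise inflate the upper mode of the histogram and push the cut above
  faint colonies — on low-contrast plates that single artefact made the
  difference between finding all colonies and finding none;
* an automatic cut below `auto_threshold_floor` (default 8 gray levels) is
  clamped up to the floor. On a plate with no stained signal the intermeans
  iteration converges *inside* the residual noise and would otherwise
  binarise noise into hundreds of fake colonies. Eight gray levels is well
  below any plausible stain signal and well above the post-blur,
  post-subtraction noise residual. User-supplied thresholds are never
  modified.

The threshold actually used is reported in the diagnostics, and batch runs
(`run_count()`) compute it once — on the first plate — and reuse it, so all
plates of a batch see the same cut.

**Region of interest.** `apply_roi()` clears everything outside a circle
inset from the dish border by `roi_margin` (default 5%) of the dish radius,
so the rim is never counted. The dish is taken to be the largest circle
fitting the image (centre of the frame, radius `min(H, W)/2`), overridable
via `dish_center`/`dish_radius` for off-centre scans. Objects *touching*
the ROI boundary are kept — the margin already excludes the rim.

**Watershed splitting.** Touching colonies merge into one binary component.
`watershed_split()` separates them on purely geometric evidence: the
Euclidean distance transform of the foreground peaks once per colony, so
its regional maxima serve as markers and every foreground pixel is assigned
to a marker by propagation. Two safeguards control over-segmentation:

* maxima closer than `min_peak_distance` (default 3 px) to a higher maximum
  of the same component are suppressed;
* the distance map is smoothed (Gaussian, sigma 1 px) before maxima
  detection, because a noise-ragged boundary otherwise splinters one
  colony's distance ridge into several spurious peaks.

A tolerance-on-saddle-depth criterion (as used by several classic
implementations) was deliberately rejected: for blur-thickened fused pairs
the saddle between the two distance peaks becomes arbitrarily shallow
(measured at ~0.7 px on rendered pairs) while the peaks stay far apart, so
peak separation is the robust signal and saddle depth is not. Fused
equal-radius disc pairs at centre distance 1.5 r split into exactly two
labels across the tested radius range (5-16 px) while single discs never
fragment.

**Measurement and filtering.** `measure_colonies()` reports, per label, the
area (pixel count; also mm^2 via `(25.4/dpi)^2` when the resolution is
known), the perimeter, the centroid, and the circularity

    circularity = 4 * pi * area / perimeter^2

which is 1 for an ideal circle and small for elongated or ragged objects.
The perimeter estimator matters because circularity is squared in it: the
outer boundary is traced (Moore neighbourhood), straight chain steps are
weighted 0.980 and diagonal steps 1.406 with a -0.091 correction per
corner (the Vossepoel-Smeulders weights), plus pi for the half-pixel
offset between the traced pixel-centre polygon and the region outline.
The estimate is floored at the isoperimetric bound `2*sqrt(pi*area)`, which
both caps circularity at 1 for near-perfect discs and supplies a perimeter
for one- and two-pixel objects whose chain is degenerate.
`filter_colonies()` then keeps detections with area in
`[min_area, max_area]` and circularity in `[circ_min, circ_max]` (defaults
0.3-1.2; `min_area = "auto"` means 20 px^2 at 600 DPI scaled by
`(dpi/600)^2`). Raising `circ_min` discards scratches and rim fragments;
the lower area limit removes debris.

When the scan carries no resolution metadata, automatic parameters fall
back to 600 DPI with a warning — a mid-range anchor for flatbed scans —
and the user can override with an explicit `dpi`.

## The size-distribution module

`build_histogram()` bins the positive areas into equal-width bins on
`[0, max * 1.001]` and normalises counts to densities integrating to 1.
The default bin count follows the Freedman-Diaconis rule clamped to
[5, 100]; the binning rule is a package choice, exposed as `n_bins`.

Two models are fitted to the bin densities at bin centres by
Levenberg-Marquardt least squares (`minpack.lm`):

* **Weibull** (`fit_weibull()`):
  `f(x) = c * (a/b^a) * x^(a-1) * exp(-(x/b)^a)` with shape `a`, scale `b`
  and amplitude `c`. The reported mean and spread derive from the shape and
  scale: `mu = b * Gamma(1 + 1/a)`,
  `V = b^2 * (Gamma(1 + 2/a) - Gamma(1 + 1/a)^2)`, `sigma = sqrt(V)`.
* **Gaussian** (`fit_gaussian()`):
  `f(x) = A/(sqrt(2*pi)*sigma) * exp(-((x - mu)/(sqrt(2)*sigma))^2)`.

Colony-size data are typically right-skewed — a treated population carries
a tail of slow-growing clones — which is why the asymmetric Weibull is the
primary model and the Gaussian serves as the symmetric comparison. No
model-selection statistic beyond the residual sum of squares is computed,
and fitting is least squares on the histogram, not maximum likelihood, by
design: the histogram is the object being summarised and plotted.

Numerical choices: the fit is initialised by the method of moments on the
binned data (the shape solved from the coefficient of variation by 1-D
root finding on `Gamma(1+2/a)/Gamma(1+1/a)^2 = 1 + cv^2`, the scale from
the mean); the amplitude starts at 1 and stays free by default — on a
proper density it converges near 1 and absorbs binning artefacts, while
`fix_c = TRUE` pins it for a strict two-parameter fit. Convergence uses
minpack's termination tests with a 500-iteration cap; an unconverged fit
is returned with `converged = FALSE`, never silently dropped. Fits need at
least five non-empty bins; fewer raise a distinct insufficient-data error
and batch runs degrade to writing the histogram alone. Residuals are
unweighted.

`weibull_moments()` is verified against numerical quadrature of the model
density to 1e-6 relative error; noiseless model histograms are recovered
to 1e-4 relative; and on sampled data (2000 draws per replicate) the
median scale-recovery error is about 1%. Fits are scale-equivariant:
multiplying all sizes by k multiplies `b` and `mu` by k and leaves `a`
unchanged, within fit tolerance.

`compare_groups()` fits each experimental arm, tabulates n, fitted mean,
fitted sigma and raw sample mean per group, and lists pairwise differences
of fitted means; groups whose fit failed are flagged and excluded from the
pairwise table. `area_from_diameter()` converts ruler-measured diameters to
areas via `pi * (d/2)^2` for comparisons with manual measurements.

## The synthetic plate generator

`generate_plate()` renders what a flatbed scanner sees: a light dish
interior on a darker scanner bed, a dark rim annulus, purple-blue stained
colonies as discs with a ~1.5 px anti-aliased soft edge, a linear
illumination gradient, and per-pixel Gaussian sensor noise, quantised to
8 bits. The stain colour weights the contrast per channel so that channel
selection is exercised non-trivially (green wins for the default stain).
Ground truth records every colony's centre, radius and ideal area.

Defaults were chosen once to represent a realistic validation plate at
this render scale: 512 x 512 px, nominal 800 DPI (so the automatic
rolling-ball radius, 20 px, exceeds the largest colony diameter), and
colony radii from lognormal(meanlog = log(8), sdlog = 0.2) — comfortably
above the roughly 5 px radius below which a blurred low-amplitude colony
drops under any sensible threshold. Single colonies are placed by
rejection sampling with at least 8 px edge clearance (a blur of sigma ~3
bridges smaller gaps, and separated colonies are the stated meaning of
"distinguishable"); a configurable fraction is instead placed as
equal-radius touching pairs at centre distance 1.5 r, the canonical fused
geometry the watershed must split. Unequal-radius pairs at that spacing
are *not* rendered because the smaller colony then contributes no distance
peak at all and no distance-based method can recover it; that regime is a
documented limitation, not a test case.

Four presets (`category_preset("#1")` ... `"#4"`) emulate plate-quality
categories from easy to hard: #1 high contrast (120 gray levels), no
touching colonies; #2 high contrast, 30% of colonies in touching pairs;
#3 low contrast (38), the same 30% touching, more noise; #4 low contrast
(32), 50% touching and a strong illumination gradient (amplitude 30).
The numeric operationalisation is this package's own; the presets preserve
the qualitative easy-to-hard ordering, and the measured mean counting
error degrades monotonically across them (roughly 0%, ~3%, ~3%, ~6% at 50
colonies per plate, 10 plates per preset — the sizes used throughout the
test suite and the acceptance script).

What the generator does *not* emulate: scanner point-spread functions,
colony-interior texture (notably the central fall-off of over-incubated
colonies), colour deconvolution of the stain, or crowded plates beyond the
placement cap. Passing tests on synthetic plates therefore demonstrate the
pipeline's correctness on its stated model of a plate — clean geometry
with known ground truth — not its accuracy on degraded real-world scans,
which the original evaluation addressed with manually counted reference
images.

## Worked example

```{r example, eval = FALSE}
library(colonysizer)

spec <- category_preset("#2", n_colonies = 50, seed = 42)
plate <- generate_plate(spec)
result <- process_plate(plate$image, pipeline_params())
result
#> <plate_result> synthetic_seed42: 50 colonies (channel G, threshold 54.1)

h <- build_histogram(result$records$area_px, n_bins = 12)
fit <- fit_weibull(h)
fit
#> <weibull_fit> a = 2.432, b = 285, c = 1.023 | mu = 252.7, sigma = 110.9 (converged)
plot(h, weibull = fit)
```

The plate truly contains 50 colonies (7 of them fused in touching pairs);
the pipeline reports 50. The fitted mean colony size (252.7 px^2) agrees
with the raw sample mean (250.2 px^2) to within 1%.

## Known limitations

* Counting accuracy is bounded by plate quality: colonies below ~5 px
  radius at default contrast, or pairs closer than the distance-peak
  geometry allows, are not recoverable.
* Circularity saturates at 1.0 for near-perfect discs because of the
  isoperimetric floor; it discriminates poorly *among* round colonies and
  is intended as a reject filter for non-round artefacts.
* 6-well plate scans must be split into single-well images upstream; the
  ROI model is one circular dish per image.
* The colony definition is purely area-based; no attempt is made to decide
  whether a colony exceeds a cell-count threshold, which would require a
  calibration from area to cell number.
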