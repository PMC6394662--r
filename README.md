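# colonysizer

Colony counting and colony-size distribution analysis for clonogenic
survival assays.

The clonogenic survival assay measures the fraction of cells that can still
found a colony after irradiation or drug treatment. Beyond the colony
*count*, the colony *size* distribution carries information about the
growth rate of surviving clones — treatments often shift the whole
distribution towards smaller colonies. `colonysizer` automates both
measurements from scanned images of stained round culture dishes:

1. **Counting pipeline** — split the RGB scan into channels and keep the
   highest-contrast one, blur (sigma calibrated to scan resolution:
   `sigma = 1.9e-6·dpi² + 6.3e-4·dpi + 1.3`), remove smooth background
   with a rolling ball (radius `0.025·dpi`), threshold (iterative
   intermeans/IsoData or Otsu), restrict to a circular region of interest
   inset from the dish rim, split touching colonies by watershed
   segmentation of the Euclidean distance transform, and filter
   detections by area and circularity, where

   `circularity = 4π·area / perimeter²`

   is 1 for an ideal circle. Per-colony areas are exported to plain-text
   files, one plate per file.

2. **Size-distribution module** — bin areas into a normalized histogram
   and fit, by Levenberg–Marquardt least squares,

   Weibull: `f(x) = c·(a/bᵃ)·x^(a−1)·exp(−(x/b)ᵃ)`, with derived mean
   `µ = b·Γ(1+1/a)` and variance `V = b²·(Γ(1+2/a) − Γ²(1+1/a))`;

   Gaussian: `f(x) = A/(√(2π)σ)·exp(−((x−µ)/(√2σ))²)`.

   Colony sizes are typically right-skewed, so the asymmetric Weibull is
   the primary model; group comparisons report fitted means ± sigma per
   experimental arm.

A synthetic plate generator renders Giemsa-like stained dishes (soft-edged
colonies, rim, illumination gradient, sensor noise) with exact ground
truth, including four quality presets from "high contrast, well separated"
(#1) to "low contrast, half the colonies touching" (#4), so every stage is
testable without image downloads.

## Worked example

```r
library(colonysizer)

spec  <- category_preset("#2", n_colonies = 50, seed = 42)  # 30% touching pairs
plate <- generate_plate(spec)
result <- process_plate(plate$image, pipeline_params())
result
#> <plate_result> synthetic_seed42: 50 colonies (channel G, threshold 54.1)

h   <- build_histogram(result$records$area_px, n_bins = 12)
fit <- fit_weibull(h)
fit
#> <weibull_fit> a = 2.432, b = 285, c = 1.023 | mu = 252.7, sigma = 110.9 (converged)
plot(h, weibull = fit)
```

The plate truly contains 50 colonies, 7 fused into touching pairs; the
pipeline counts 50 — the green channel was auto-selected, the automatic
threshold landed at 54.1 gray levels, and the watershed split every pair.
The fitted mean colony size, µ = 252.7 px², matches the raw sample mean
(250.2 px²) within 1%; sigma = 110.9 px² describes the spread of the
fitted distribution.

Batch work goes through `run_count()` / `run_fit()` / `run_simulate()`, or
the command-line front end:

```sh
inst/cli/colonysizer simulate --preset '#1' --seed 5 --out plates/
inst/cli/colonysizer count --input 'plates/*.png' --out counts/
inst/cli/colonysizer fit --input 'counts/*_sizes.txt' --out fits/
```

Every batch writes its fully resolved parameters (including auto-computed
sigma, rolling-ball radius and threshold, frozen on the first plate) next
to its outputs, so runs are reproducible.

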