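---
title: "Scoring soybean flooding injury from UAV imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring soybean flooding injury from UAV imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodscore)
```

## The problem and the measurement model

Flood tolerance in soybean breeding is rated per plot with a five-level
flooding injury score (FIS): 1 means no apparent injury, 5 means most
plants severely injured or dead. `floodscore` estimates FIS from five
plot-level image features measured by a UAV flying at 20, 50 or 80 m:

* **canopy temperature** (°C): flooded, injured plants close stomata,
  transpire less and run hotter; the feature is the mean thermal-pixel
  value over the canopy mask;
* **NDVI** `(NIR − R)/(NIR + R)` on reflectance: greenness/health proxy,
  averaged over the canopy mask (pixels with `NIR + R = 0` are undefined
  and excluded);
* **canopy area, width, length** (pixels): area is the count of canopy
  pixels after background removal, length the number of occupied image
  rows (the along-row axis), width the number of occupied columns.

A 5-input, 10-hidden-neuron, 1-output feedforward network (tanh hidden
layer, linear output; 71 trainable parameters) regresses FIS on these
features; its continuous output is binned to the five levels
(`[0,1.5)→1 … [4.5,∞)→5`, negatives clipped to 1) and scored by percent
accuracy on a held-out 10% test set.

## Synthetic study conditions

No deposited imagery exists for this problem, so the package generates its
own field; the generator is first-class, tested code and its defaults *are*
the study conditions of the analysis.

* 724 single-row plots; FIS drawn with proportions
  (0.18, 0.27, 0.27, 0.18, 0.10) — a plausible unimodal score histogram,
  configurable.
* Each plot is an 80 × 40 pixel multispectral ROI at 20 m
  (13.2 mm/pixel); the thermal grid is coarser (23.4 mm/pixel) and never
  resampled onto the multispectral grid. The ROI is a stylised mini-plot:
  pixel geometry, not the full 2.13 m field row, is what matters to the
  algorithms.
* Three ground classes: **canopy** (an elongated super-ellipse along the
  row axis, exponent 4, aspect tied to the ROI, with a smooth-noise
  boundary), **sunlit soil** (52.3 °C, NDVI 0.10) and **shaded
  soil/residue** (48.5 °C, dark in all bands), assigned blockwise
  (~10 cm cells) so contiguous pure-soil patches exist for reference
  measurements. The shadow share of the background (0.763) makes the
  pooled background average 49.4 °C; at 4 pm with a closed mid-season
  canopy most inter-row ground is shaded, and a shaded-ground temperature
  a few degrees below sunlit soil keeps the thermal histogram bimodal —
   which 2-cluster K-means requires. A shadow mode midway between canopy
  and soil would occasionally make K-means merge canopy and shadow on
  small, hot (FIS 5) canopies.
* FIS-conditional canopy means at 20 m: temperature
  37.25–41.25 °C in 1 °C steps, NDVI 0.615–0.375 in 0.06 steps, area
  fraction 0.60–0.25. Under the default FIS mixture these yield field-wide
  means of 39.0 °C and NDVI 0.51. Canopy NIR/red pairs are solved from the
  target NDVI at band sum 0.45, so the zero-noise NDVI is exact by
  construction.
* **Canopy porosity** 0.15: the canopy envelope is punched with sunlit
  gaps at two scales — leaf-scale gaps (~2 px) and between-plant bare
  patches (~8 px ≈ 10 cm). At 20 m both are resolved, so K-means rejects
  them from the thermal canopy cluster and color segmentation removes
  them; at 50 m the fine gaps blend into canopy pixels; at 80 m both do.
  This resolution-dependent blending, not atmosphere, is what makes
  *apparent* canopy temperature rise and NDVI fall with flight height.
* Noise: per-pixel reflectance SD 0.012, thermal SD 0.5 °C; between-plot
  random effects SD 0.30 °C (temperature), 0.02 (NDVI), 0.02 (area
  fraction). These keep adjacent FIS classes overlapping at plot level
  without swamping the class structure.
* Raw captures: `DN = round(clip(reflectance · illumination_b · gain_b ·
  exposure_b · 65535))` per band with a flat vignette, plus a panel capture
  of known reflectance 0.49 rendered under the same model. The per-band
  illumination (1.05, 1.10, 1.00, 0.95, 0.90) is exactly what panel
  calibration must divide out; gains/exposures (0.8, 0.6) keep the dynamic
  range clear of clipping so round trips are quantization-exact.

### Flight-height degradation

50 and 80 m are realised from the 20 m truth by (i) exact area-average
downsampling by the GSD ratio (defaults 13.2/34.7/55.6 mm/px
multispectral, 23.4/68.0/108.8 mm/px thermal, deliberately not exactly
proportional to height, as delivered camera specifications rarely are),
(ii) a per-height Gaussian
sensor PSF on the thermal raster (SD 0.25 px at 50 m, 0.9 px at 80 m), and
(iii) thermal attenuation `T_obs = tau·T + (1 − tau)·33.4 °C` with
tau(50) = 0.9259 and tau(80) = 0.7989, solved so pure-soil means fall
52.3 → 50.9 → 48.5 °C at the 33.4 °C ambient. The truth mask is
downsampled by majority vote, class maps by plurality.

The blur and porosity values were calibrated once, jointly with the
attenuation, so the generator reproduces the qualitative field behaviour
the analysis assumes: apparent canopy temperature *rises* with height
(mixed pixels and blur beat attenuation), soil temperature *falls*
(attenuation alone), NDVI *falls* (mixing with soil). They are documented
as tuned, not physical. For the hottest, smallest canopies the two thermal
effects nearly cancel between 50 and 80 m, so the per-plot direction is
tested as holding for ≥90% of plots while the field means are strictly
ordered.

## Calibration

`dn_to_radiance` inverts the sensor part of the forward model
(`radiance = DN/(gain·exposure·65535)`). The **unified-factor** method
computes one factor per band, `known_reflectance / panel_radiance`, with
the panel radiance summarised over the central 50% crop of the panel
capture (standing in for the interactive panel crop); it is
exposure-invariant by construction, and out-of-range results are clipped
to [0,1] with a recorded count. The **max-min** method rescales DN by the
16-bit range; it is monotone and robust to exposure auto-compensation but
is not absolute reflectance. NDVI from the two methods coincides exactly
when the per-band total scale is equal across NIR and red (the ratio
cancels), which the tests verify on constructed inputs.

## Background removal

The stepwise multispectral procedure uses fixed numeric keep-boxes
(`threshold_set()`), frozen once against the default class spectra —
reproducibility is preferred over fidelity to thresholds that were
originally drawn freehand in an interactive tool:

1. YCbCr box on the (red, NIR, red-edge) composite, mapped to (R, G, B) in
   that order (the mapping is configurable; the source procedure does not
   state it). The Cb lower bound 0.500 separates sunlit soil (Cb ≈ 0.48)
   from canopy (Cb ≈ 0.53) and removes the bulk of the soil.
2. YCbCr box on the true-color composite; its luma upper bound 0.21
   removes remaining bright soil near the canopy.
3. HSV box on the true-color composite; the value lower bound 0.075
   removes dark pixels (shadow, fallen leaves).
4. Components smaller than 1% of the image (8-connectivity, strict `<`)
   are removed as noise.

Each step's mask is a subset of the previous one, per-step removal counts
are logged, and an empty mask at any step warns and flags the plot invalid
(mirroring dead plots). On noise-free scenes the final mask equals the
generator truth exactly; under default noise the Jaccard overlap is ≥0.95
for ≥95% of plots (regression-tested at fixed seed).

Thermal masks use 1-D K-means with k = 2 on temperature values
(k-means++ seeding under a fixed seed, then the standard iteration),
taking the *lower-mean* cluster as canopy, so the result is invariant to
cluster label order. A constant raster is an error (no separation).
CIE Lab is implemented for completeness of the color-space menu but unused
by the default procedure.

## Group statistics

`group_compare()` delegates to `aov` and `TukeyHSD` (alpha = 0.05) and
derives the compact letter display by the standard insert-absorb
algorithm, groups ordered by descending mean, ties by label. All-constant
input is reported as F = 0, p = 1 with a single shared letter rather than
an error. Height comparisons treat the three heights as independent
groups (the repeated-measure structure of re-flying the same plots is
deliberately not modelled).

## Network training

Levenberg–Marquardt least squares on the scaled features (per-feature
min-max to [−1, 1], fitted on the training split only; constant features
map to 0 with a warning). Each epoch forms the exact Jacobian of the
residuals with respect to all 71 parameters and solves
`(JᵀJ + mu·I)δ = Jᵀr`; an accepted step (SSE decreases) multiplies mu by
0.1, a rejected one by 10 and retries. Defaults (epochs ≤ 1000, goal 0,
max_fail 6, min_grad 1e-7, mu0 0.001, mu_max 1e10) follow the standard
damped Gauss-Newton parameterisation; mu is the damping parameter, not a
learning rate. Training stops on epochs, goal, gradient norm, mu overflow, or six
consecutive validation failures — the validation set is 10% carved from
the training partition, and early stopping restores the best-validation
weights. Initialisation is seeded uniform [−0.5, 0.5] scaled by
1/sqrt(fan-in); the classical Nguyen–Widrow scheme is deliberately not
reproduced (a documented simplification). The 90/10 split uses floor
rounding (724 → 72 test records) and the validation carve-out floor as
well; top-fraction selection uses ceiling (72 → 8 at 10%, 15 at 20%),
ranking ascending by raw output with ties broken by plot id. Records from
empty-canopy plots are excluded before splitting. One model is fitted per
flight height.

## What passing tests do and do not show

The generator emulates the *statistical* structure the pipeline relies on:
class-separable spectra, FIS-ordered feature means, resolution-dependent
mixing, attenuation, per-band sensor scales. It does not emulate
orthomosaic stitching or registration error, sun-angle or BRDF effects,
within-field soil gradients, plant 3-D structure, or real spectral
variability; canopy shapes are stylised super-ellipses. Passing the suite
therefore shows the algorithms are implemented correctly and recover known
truth under realistic noise — not that the trained network transfers to
real fields. On the default synthetic field the five features separate the
FIS classes more cleanly than real imagery would, and the test accuracy
(computed by the acceptance script, not quoted here from elsewhere)
should be read with that in mind.

## Numerical and degenerate-input choices

* Problem sizes: the shipped checks use the full 724-plot field for the
  parameter-recovery and classification runs (about a minute end to end)
  and 30–60-plot fields for property tests.
* Identical configuration + seed gives bit-identical fields, splits and
  fits; all RNG use is localised and restores the caller's RNG state.
* Area-average resampling is exact (fractional overlap weights), verified
  against a brute-force overlap oracle.
* DN quantization bounds calibration round-trip error at
  `0.5/(illumination·gain·exposure·65535)` per band; tests assert 1e-4.
* Empty canopy anywhere propagates a `valid = FALSE` record rather than an
  error; `canopy_geometry` returns zeros, means return `NA`.
* `bin_fis` rejects non-finite input; `kmeans_thermal_mask` rejects
  constant rasters; `split_dataset` requires n ≥ 10.
* The unused green band of the NDVI definition is carried in the data
  model but never consumed, matching the feature definitions.
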