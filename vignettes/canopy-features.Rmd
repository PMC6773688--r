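---
title: "Canopy color and texture features: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy color and texture features: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyfeat)
```

`canopyfeat` condenses an 8-bit RGB image of a plant canopy into 455
numeric features plus two covariates. This vignette is the package's
account of the method: what each stage assumes, which knobs matter, the
numerical conventions that make results bit-reproducible, and what the
synthetic validation does and does not demonstrate.

## The per-image procedure

### Contrast stretching

Raw field images vary in exposure and white balance. Each channel is
independently remapped so that its 1st percentile goes to 0 and its
99th to 255 (bottom and top 1% of pixels saturate), which normalizes
the dynamic range across images without any reference target.
Percentiles are computed by linear interpolation between order
statistics (R's default quantile definition); on images of any
realistic size, alternative percentile conventions move the limits by
less than one gray level. Two conventions are pinned for exactness:

* remapped values are rounded **half away from zero** back to integers
  (`round_half_away()`); base R's round-half-to-even would differ on
  exact halves such as 127.5;
* a **flat channel** (lower limit = upper limit) has an undefined
  stretch slope and is returned unchanged.

The stretch is monotone within a channel, so it never reorders pixels.

### Segmentation

One global threshold on a single index struggles across lighting and
shadow conditions, so the mask combines two routes computed on the
stretched image:

* **M1**: Otsu's threshold on the difference between the rescaled
  modified excess green (MExG) and rescaled color index of vegetation
  extraction (CIVE) images. Vegetation is MExG-high and CIVE-low, so
  the difference enhances the plant/soil separation; plant pixels are
  those **strictly above** the threshold. The polarity is a package
  decision — either side could be argued from the construction — and is
  fixed and tested.
* **M2**: rescaled excess green (ExG) strictly above 0.5
  (`exg_threshold`). Ties at exactly 0.5 go to background; the choice
  is arbitrary and has measure-zero effect on real images.

The final mask is the **union** (1 where either mask fires, NA where
both are 0). NA — not 0 — marks background so that masked pixels simply
drop out of every later statistic instead of piling up mass at zero.
Connected objects of `min_object_pixels` (default 300, **inclusive**)
or fewer pixels are then removed as noise, under 8-connectivity by
default (`connectivity = 4` available). Holes inside plant regions are
*not* filled: a within-canopy soil gap is genuine background.

Otsu's method is applied to the difference image binned into 256 levels
with the same rounding rule as the texture quantizer; the split
maximizes between-class variance, ties resolved to the smallest
threshold. The difference image is not itself rescaled first — Otsu is
invariant to affine rescaling, so it would change nothing. A constant
difference image has no threshold and the image is flagged invalid.

### The 35-transform bank

Each stretched image yields (1 + 4) × 3 + 20 = 35 rasters: R, G, B
themselves; X, Y, Z / L\*, a\*, b\* (CIE, D65, 2° observer), H, S, I,
and Y′, Cb, Cr; and 20 vegetation indices defined as closed-form
arithmetic on the R, G, B values. ExG is not a member: min–max rescaled
it is identical to the normalized green NG = G/(R+G+B) (ExG = 3·NG − 1),
which is — a property the test suite checks rather than assumes.

Color-space conventions are not fully determined by the channel names,
so the package pins and exposes them:

* **XYZ / L\*a\*b\***: stretched 8-bit values are treated as nonlinear
  sRGB and pass through the standard sRGB inverse companding before the
  D65 linear matrix; XYZ are scaled so white is (95.047, 100, 108.883).
  This is the only defensible default for consumer webcam imagery, but
  `assume_linear_rgb = TRUE` skips the companding for calibrated linear
  input.
* **HSI**: the Gonzalez & Woods variant — I = (R+G+B)/3 scaled to
  [0, 1], S = 1 − 3·min(R,G,B)/(R+G+B), H from the arccos form in
  degrees [0, 360), with H = 0 where undefined (neutral pixels).
* **Y′CbCr**: ITU-R BT.601 full-range coefficients on 8-bit values.

Ratio indices divide by zero on some pixels (e.g. G/R with R = 0 after
stretching). The transforms deliberately let NaN and ±Inf through and a
single sanitization pass replaces NaN and −Inf with the raster's
minimum finite value and +Inf with its maximum, before masking. Values
stay in double precision throughout; nothing is rounded at this stage.

### Color features (140)

Four moment statistics per transform over the N plant pixels: mean,
standard deviation, skewness, kurtosis — all with **population**
denominators (divide by N). The camera sees essentially the whole
canopy of a plot, so its pixels are treated as the population rather
than a sample. Kurtosis is the raw fourth standardized moment, so a
Gaussian scores 3 and the lower bound is 1. On a constant transform
σ = 0 and skewness/kurtosis are 0/0: they are reported NA. Any numeric
stand-in would fabricate shape information; how to impute NA columns is
the modeller's decision, not the extractor's.

### Texture features (315)

Texture is read from gray-level co-occurrence matrices (GLCMs). Each
transform — **unmasked**, so the gray scale stays anchored to the whole
image rather than to whatever the mask kept — is min–max rescaled to
0–255 and rounded to integers (half away from zero), then masked. All
256 gray levels are retained: fewer levels are common practice to save
time, but coarser quantization discards information, and the level
count is exposed (`glcm_levels`) for experimentation.

Two symmetric GLCMs are accumulated at displacement d = 1 along 0° and
90° (45°/135° available via `glcm_directions`); every valid pixel pair
increments both (i, j) and (j, i), and pairs containing an NA are
skipped. After normalization to probabilities, nine statistics are
computed — maximum probability, mean, variance, correlation, angular
second moment, entropy (base-2 log, 0·log 0 = 0), dissimilarity,
contrast, inverse difference moment — using the single-margin forms of
mean and variance, which are valid precisely because the GLCM is
symmetric (both margins coincide). The two directions' statistics are
averaged element-wise, which makes the features invariant to image
transposition (checked by test). GLCM correlation is NA when the GLCM
variance is 0 (constant quantized region, a 0/0). If any transform has
no valid pixel pair at all, the whole image is flagged invalid rather
than partially filled, keeping the feature table rectangular.

### Covariates, batching, correlation

`location` is a user-supplied integer site code (1–4 in the intended
use) — it is never inferred from the image. `time` is the plain
calendar-day difference between planting and measuring dates (endpoints
not counted inclusively). Batch runs write a CSV (NA spelled `NA`, full
double precision) plus a JSON sidecar with the exact configuration, and
failed images are retained as flagged rows for auditability.
`feature_correlation()` returns the 455 × 455 Pearson matrix over valid
rows (pairwise-complete observations; constant columns give NA), the
basis for inspecting redundancy among the transforms.

## The synthetic scene generator

Real canopy imagery is not shipped with the package, so validation runs
on generated scenes (`generate_scene()`): a brown soil background
(default mean RGB (120, 95, 70)) under multiplicative Gaussian
illumination noise, overlaid with randomly placed and rotated green
ellipse leaflets (default mean (60, 150, 55), per-leaf color jitter,
per-pixel additive noise, optionally 3-lobed clusters mimicking
trifoliolate leaves), plus optional darkened circular shadow patches.
The truth mask is exactly the union of rendered ellipses, and the
generator never consults the segmentation code or its thresholds, so
scoring the segmenter against the truth is a genuine end-to-end check.
Scenes are bit-reproducible from (parameters, seed), down to PNG bytes.

Default leaflet semi-axes are 16–24 px so a single leaflet exceeds the
300-pixel cleaning floor. The default resolution is 320 × 240: the
generator emulates the *content* of early-vegetative canopy imagery
(two-mode index histograms, leaf-scale texture, 30–50% cover), not the
resolution of any particular camera; full-size scenes are just a
parameter away but add nothing to the properties under test. The
validation suite uses 320 × 240 scenes, 200 random ≤ 16 × 16 images for
the GLCM oracle, and 64 × 64 rasters for the moment oracle.

What passing these tests shows: the arithmetic of every stage matches
independent brute-force oracles, and the segmentation recovers
ground-truth masks (IoU ≥ 0.95 on easy scenes) when foliage and soil
are separable in ExG/MExG/CIVE space. What it does not show: performance
on real images with specular highlights, mixed pixels at leaf edges,
senescent or stressed (non-green) tissue, green weeds, or uncalibrated
color drift between images — the "hard" preset (desaturated leaves,
shadows) is reported diagnostically, with no accuracy claim.

## Parameter summary

| Parameter | Default | Unit | Notes |
|---|---|---|---|
| `exg_threshold` | 0.5 | rescaled ExG | mask M2 cutoff, strict `>` |
| `min_object_pixels` | 300 | pixels | inclusive removal floor |
| `connectivity` | 8 | — | object labelling neighbourhood |
| `assume_linear_rgb` | FALSE | — | skip sRGB companding before XYZ |
| `glcm_levels` | 256 | gray levels | texture quantization |
| `glcm_d` | 1 | pixels | co-occurrence displacement |
| `glcm_directions` | 0°, 90° | degrees | averaged; 45°/135° optional |

## Known limitations

* No color calibration: identical pixel values may represent different
  physical colors across images; the contrast stretch normalizes range,
  not chromaticity.
* The segmentation assumes green-on-brown scenes; it will misbehave on
  purple-leaved genotypes or green backgrounds.
* Feature values depend on the pinned color-space conventions; imagery
  from calibrated linear sensors should set `assume_linear_rgb`.
* The 455 features are heavily inter-correlated by construction (all
  derive from three bands); downstream modelling should expect, and be
  robust to, that collinearity.
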