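---
title: "Texture analysis of equine thermograms: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture analysis of equine thermograms: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(equitherm)
library(dplyr)
```

## The problem

Infrared thermography (IRT) renders the radiant energy emitted by a horse's
body surface as a pseudo-color temperature map. After exercise, working
muscles release most of their energy as heat, so the thoracolumbar surface
warms — but conventional measures of a region of interest (maximal
temperature `Tmax`, mean temperature `Taver`) are unspecific: they respond
to ambient conditions, coat state and many other influences. The idea this
package implements is to look instead at the *texture* of the thermogram —
second-order spatial statistics of the pseudo-color image — and to ask
which texture descriptors track established blood biomarkers of exercise
effect across repeated standardized exercise.

The study layout is 12 horses x 6 daily exercise repetitions (RE) x 2
sampling times per repetition (BS 0 at rest, BS 1 immediately after
exercise), giving 144 thermograms, each segmented into four regions: ROI 1
(withers), ROI 2 (thoracic spine), ROI 3 and ROI 4 (left and right back
muscles). At each sampling a 12-parameter blood panel is drawn; white
blood cell count (WBC), creatine phosphokinase (CPK) and aspartate
aminotransferase (AST) accumulate across repetitions and serve as the
reference biomarkers of exercise effect.

## The processing chain

1. **Color decomposition.** Each 8-bit RGB thermogram is decomposed into
   the 12 components of four color models: RGB (R, G, B), YUV (Y, U, V),
   YIQ (Y, I, Q) and HSB (H, S, B). YUV/YIQ use the BT.601 luma weights
   (0.299, 0.587, 0.114) and the standard chrominance matrices; HSB uses
   the hexcone model. The signed chrominance planes are mapped affinely so
   the achromatic value sits at the center of the 8-bit gray range; hue is
   linearized from degrees onto the gray range.
2. **Normalization.** Each component yields two gray-level channel
   variants: un-normalized (capital letter, e.g. `R`) and normalized
   (lowercase, e.g. `r`) via
   `I_OUT = round(2^n (I_IN - MIN)/(MAX - MIN)) + 1`, clamped to
   `[1, 2^n]`, with bounds derived from the region pixels under one of
   three schemes: `mu3sigma` (`mu +/- 3 sigma`), `minmax`, or `perc1_99`
   (1st/99th percentiles). The default normalized variant is `minmax`
   (which scheme the lowercase channels use is a config knob).
3. **Texture features.** 88 features from eight approaches per channel
   variant per region: histogram statistics (14), gradient map (6), causal
   autoregressive model (5), Gabor transform (24), histogram of oriented
   gradients (8), gray-level run-length matrix (7), and symmetric (GLCM,
   12) and asymmetric (GLCH, 12) gray-level co-occurrence matrices. That
   is 88 x 24 = 2112 combinations per region, and 528 feature/biomarker
   pairs per color model.
4. **Selection by slope parallelism.** For each (biomarker, feature,
   region), simple regressions of both series on the repetition index at
   BS 1 (horses as replicates) are compared by the ANCOVA
   extra-sum-of-squares F-test. If the slopes are indistinguishable
   (p > 0.05), a pooled slope is fitted and the intercepts compared the
   same way. A feature is *related* to a biomarker when the slopes are
   parallel and both series individually show a significantly non-zero
   slope (the "evidence of linearity" gate).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `color.bit_depth` | 8 | gray levels `1..2^n` of channel images |
| `color.glcm_bit_depth` | 6 | requantization for GLCM/GLCH/GRLM (co-occurrence at 256 levels is sparse and slow on small regions) |
| `color.normalization` | `minmax` | scheme of the lowercase channel variants |
| `glcm.distances` | 1..9 | pair distances, averaged with the 4 directions into one 12-vector |
| `glcm.log_base` | e | entropy logarithm (2 for bits) |
| `stats.alpha`, `stats.alpha_nz` | 0.05 | slope/intercept equality and non-zero slope levels |
| `stats.scale` | `align` | feature-to-biomarker scale alignment (below) |
| `stats.p_adjust` | `none` | per-pair testing at `alpha`; `BH` optional |

Gabor kernels use wavelengths {4, 6, 8, 12, 16, 24} px with an isotropic
Gaussian envelope of sigma = lambda/2, truncated at 3 sigma, DC-corrected,
with orientations H/V/N/Z (0/90/45/135 degrees); responses are averaged
over region pixels whose full kernel support lies inside the image, which
avoids border bias on small regions at the cost of `NA` for wavelengths
whose support exceeds the raster.

## Scale alignment

A texture feature (gray-level units) and a biomarker (e.g. U/L) are not
commensurate, so comparing their slopes needs a convention. The default
mode (`align`) maps the feature
series affinely to the biomarker's sample mean and variance before the
slope comparison; after this alignment, slope equality is equivalent to
equality of the correlation with the repetition index, which is the
scale-free notion of "tracking the same trend". The `raw` mode reproduces
a direct comparison of unscaled slopes.

## The synthetic-data generator

Raw thermograms from such studies are rarely deposited, so the generator
produces studies with precisely the statistical structure the analysis
assumes:

* **Baseline surface**: resting temperature 30 deg C, a per-horse offset
  (SD 0.4), a fixed smooth gradient (amplitude 0.8), pixel noise (SD 0.2).
* **Acute warming**: at BS 1, a smooth plateau of +2 deg C over the
  withers and both back-muscle regions (ROI 1/3/4), constant across
  repetitions — mirroring the observation that `Tmax`/`Taver` are elevated
  after every exercise bout but carry no across-repetition trend.
* **Cumulative heterogeneity (the texture driver)**: at BS 1, small
  Gaussian patches (amplitude +/-1.5 deg C with random sign — warm muscle
  spots and cool sweat patches — footprint sigma ~2-3 px) are scattered
  inside each muscle region. Their count grows linearly with a latent
  level `re + noise`, so the spatial temperature variance grows linearly
  across repetitions while the region mean is unaffected. Patches are
  confined to their own region, leaving the spine region (ROI 2) as a
  clean uncoupled reference.
* **Biomarkers**: WBC/CPK/AST at BS 1 follow
  `baseline + slope x re + noise` with slopes 0.44, 18.4, 14.2 per RE,
  calibrated so that, e.g., mean CPK rises from ~202 U/L at the first to
  ~294 U/L at the sixth repetition with an SD around 65-70 U/L at n = 12.
  RBC/HGB/HCT/LAC jump at BS 1 within every repetition without a trend;
  LAC is floored at the 1.0 mmol/L detection limit; the remaining panel
  parameters fluctuate around resting values.

The latent driver noise (SD 2.0 between horses + 2.0 per observation, in
repetition units) was chosen so that the *observable* feature series —
red-channel variance over a muscle region, which also carries the sampling
noise of a variance estimate — has the same residual-to-slope ratio
(~3.5 RE units) as the coupled biomarkers (~3.4 for CPK). This makes the
generator's claim "feature and biomarker share one trend up to independent
noise" true for what the pipeline actually measures, which is exactly what
the recovery tests exercise.

The default render range (15-55 deg C) places the physiological skin range
on the palette's green-to-yellow segment, where the red channel rises
linearly with temperature; red-channel variance then responds linearly to
temperature heterogeneity. The raster defaults to 120 x 160 px (the
detector size of the entry-level camera class used for such studies);
simulation-heavy tests use a 60 x 80 raster, which preserves all the
statistical structure at a quarter of the pixel count.

**What the generator does not emulate**: anatomy (regions are ellipses,
not horse outlines), physiological thermoregulation dynamics, ambient
drift, coat and moisture effects, camera fixed-pattern noise, or motion
blur. Passing recovery tests therefore demonstrate that the *pipeline*
recovers a known coupling from images with realistic first- and
second-order statistics — not that real thermograms carry such couplings.

## Numerical choices and degenerate inputs

* Rounding in the normalization formula is round-half-up, then clamping:
  the printed formula yields `2^n + 1` at the maximum, and clamping
  preserves the stated bit depth. A constant plane under a data-driven
  scheme is flagged degenerate and mapped to the all-1 image.
* Histogram skewness/kurtosis of a constant region are defined as 0; all
  percentiles are the smallest gray level whose CDF reaches the quantile.
* The causal autoregressive fit uses the minimum-norm least-squares
  solution for rank-deficient designs, so a constant region gives
  theta = (1/4, 1/4, 1/4, 1/4) and sigma = 0.
* Co-occurrence conventions: `0 log 0 = 0`; correlation of a
  zero-variance matrix is 0; offsets with no valid pixel pair are skipped
  in the direction/distance average; `Area` is the raw count of pairs
  (doubled in the symmetric variant, which counts both orderings).
* GRLM "moment" features are the non-uniformities divided by the run
  count (dimensionless in run count); the dominant/maximum histogram
  features use bin widths 1 and 10 with counts normalized by region area.
  Both are interpretations of under-documented feature names and are
  config-exposed.
* The slope-parallelism F-tests are computed in closed form from
  per-group regression sums; an exactly-identical pair of series returns
  F = 0, p = 1 (guarded against floating-point noise). Degenerate feature
  series (constant, or with missing values from a failed family) are
  reported with `related = NA` rather than dropped silently.
* Hue is treated as an ordinary linear gray channel, not circularly; for
  rainbow-palette thermograms hue spans well under a full turn, so the
  wrap-around case does not arise in practice.

## Design decisions that were genuinely open

* The conventional channel naming collides across models (B = blue and
  brightness; Y appears in YUV and YIQ), so the feature table carries an
  explicit `model` column; the 12 components are the union of the four
  3-component models with Y counted once per model.
* The `related` gate uses each series' own non-zero slope test rather
  than the pooled slope's: pooling a flat feature with a strongly trending
  biomarker yields a significant pooled slope, which would declare flat
  features "related" and defeat the selection's purpose. Requiring
  evidence of linearity from each series individually is the reading that
  makes the criterion meaningful.
* No multiple-testing correction is applied across the 2112 pairs by
  default, matching per-pair testing at p < 0.05; Benjamini-Hochberg is
  available behind `stats.p_adjust`.
* The eight-point magenta palette variant is available
  (`rainbow_palette("magenta8")`) for conventions that annotate
  medium-high temperatures in magenta; the default seven-point palette
  ends blue -> ... -> red -> white.

## Problem sizes used in validation

The test suite validates feature families against independent brute-force
oracles on 200 random 12 x 12 images at 4 gray levels (plus 80 x 80 images
for the Gabor bank, whose smallest kernel support exceeds 12 px); the
slope-equality test's type-I error on 2000 null simulations at the study's
own n (72 points per series); and coupling recovery on 100 synthetic
studies at the default design with a 60 x 80 raster. `scripts/acceptance.R`
re-runs the same computations from scratch and writes the headline numbers
as JSON.

## A worked example

```{r example, eval = FALSE}
study <- generate_study(study_design(image_height = 60, image_width = 80),
                        effect_model(), seed = 1)
cfg <- pipeline_config(texture = list(families = "HS", channels = "R"))
features <- extract_features(study, cfg, conventional = FALSE)
selection <- select_related(features, study$biomarkers, targets = "CPK")
dplyr::filter(selection, feature == "HS.Variance", channel == "R")
plot_selection_matrix(selection)
```

## Known limitations

* Radiometric camera files are out of scope; temperature fields arrive as
  float rasters (or are recovered from the rendered image by palette
  inversion, which is quantization-limited).
* The full 8-family extraction is a few tens of seconds per 120 x 160
  thermogram in pure R; the Gabor and co-occurrence families dominate.
  Family and channel subsets (`texture.families`, `texture.channels`)
  make targeted analyses fast.
* Published regression slopes from the original study depend on its raw
  data, which are not publicly deposited; the package validates against
  combinatorial counts, closed forms, oracle equivalence and parameter
  recovery instead.
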