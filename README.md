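# equitherm

Advanced texture analysis of pseudo-color infrared thermograms of the
equine thoracolumbar region across repeated exercise, and selection of the
texture features whose across-repetition trends parallel blood biomarkers
of exercise effect.

## The problem

Conventional thermography summarizes a region of interest by its maximal
and mean temperature (`Tmax`, `Taver`). These respond to exercise but are
unspecific. This package implements the alternative: decompose the
rendered thermogram into the 12 components of four color models (RGB,
YUV, YIQ, HSB), normalize the gray levels, and compute **88 texture
features** from eight approaches — histogram statistics (HS), gradient
map (GM), causal autoregressive model (AM), Gabor transform (GT),
histogram of oriented gradients (HOG), gray-level run-length matrix
(GRLM), and symmetric/asymmetric gray-level co-occurrence matrices
(GLCM/GLCH) — per region: 88 x 24 channel variants = 2112 combinations
per region of interest.

A texture feature is then declared **related** to a biomarker (WBC, CPK
or AST, which accumulate over repeated standardized exercise) by ANCOVA
slope parallelism. With repetition index $x$ and series $y_g = a_g +
b_g x + \varepsilon$ for the biomarker and the (scale-aligned) feature,
the extra-sum-of-squares F-test compares the separate-slopes model
against the common-slope model:

$$F = \frac{SSE_{common} - SSE_{separate}}{SSE_{separate} / (n - 4)}$$

If $p > 0.05$ the slopes are parallel and a pooled slope is fitted, then
the intercepts are tested the same way. The pair is flagged related when
the slopes are parallel and each series individually shows a non-zero
slope (evidence of linearity).

Because real radiometric data for such studies are rarely deposited, the
package includes a first-class synthetic study generator
(`generate_study()`): temperature fields with post-exercise warming and a
cumulative spatial-heterogeneity driver coupled to the biomarker trends,
rendered through a rainbow palette, with region masks and a 12-parameter
blood panel — the exact structure the selection procedure is designed to
recover.

## Worked example

```r
library(equitherm)

study <- generate_study(study_design(image_height = 60, image_width = 80),
                        effect_model(), seed = 1)
study
#> <irt_study> 12 horses x 6 RE x 2 BS = 144 thermograms (60 x 80 px)
#>   regions: ROI1=237px ROI2=194px ROI3=444px ROI4=444px
#>   biomarkers: 144 rows x 12 parameters

cfg <- pipeline_config(texture = list(families = "HS", channels = "R"))
features <- extract_features(study, cfg, conventional = FALSE)
selection <- select_related(features, study$biomarkers, targets = "CPK")
dplyr::filter(selection, feature == "HS.Variance", channel == "R")
#>     roi biomarker channel feature     p_slope_equal pooled_slope p_slope_nonzero related
#>   1   1 CPK       R       HS.Variance       0.816           20.6      0.00000508 TRUE
#>   2   2 CPK       R       HS.Variance       0.00810         NA        0.474      FALSE
#>   3   3 CPK       R       HS.Variance       0.714           21.0      0.00000508 TRUE
#>   4   4 CPK       R       HS.Variance       0.688           21.1      0.00000508 TRUE
```

Reading the output: in the withers and back-muscle regions (ROI 1, 3, 4)
the red-channel histogram variance rises across the six exercise
repetitions with a slope statistically indistinguishable from CPK's
(`p_slope_equal` > 0.05), the pooled slope is ~21 CPK-scale units per
repetition and significantly non-zero — the feature tracks the muscle
biomarker. Over the thoracic spine (ROI 2), where the generator places no
cumulative heterogeneity, parallelism is rejected and the feature's own
slope is flat (`related = FALSE`).

The full pipeline (simulate -> extract all 8448 rows per image -> select,
with artifacts and a run log on disk) is one call:

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
```

or from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/equitherm.R run --config cfg.yaml --seed 1 --out-dir out
```

Useful entry points: `temperature_to_rgb()` / `rgb_to_temperature()`
(rainbow-palette rendering and inversion), `decompose_channels()` /
`normalize_plane()` (color models and gray-level normalization),
`hist_features()` ... `glcm_features()` (the eight families),
`roi_temperatures()` (conventional measures), `route_test()` /
`compare_bs()` / `compare_re()` (the routed statistical comparisons),
`fit_parallelism()` with `tidy()`/`glance()`/`autoplot()` methods, and
`plot_selection_matrix()` for the summary view. The methods vignette
(`vignettes/equine-thermogram-texture.Rmd`) documents the models,
parameters and design choices.

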