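#' Study design for a synthetic repeated-exercise thermography study
#'
#' Describes the factorial layout the generator emulates: `n_horses` animals,
#' each undergoing `n_re` daily standardized exercise repetitions (RE), with
#' two sampling times per repetition (BS 0 at rest before exercise, BS 1
#' immediately after). The default design (12 horses x 6 RE x 2 BS) yields
#' 144 thermograms. The raster defaults to 120 x 160 px, the detector size
#' of common entry-level thermal cameras.
#'
#' @param n_horses Number of horses (>= 1).
#' @param n_re Number of exercise repetitions (>= 2).
#' @param n_bs Sampling times per repetition; must be 2 (BS 0 / BS 1).
#' @param image_height,image_width Raster dimensions in pixels.
#' @return A list of class `study_design`.
#' @examples
#' study_design()               # the default 12 x 6 x 2 layout
#' study_design(n_horses = 2, image_height = 60, image_width = 80)
#' @export
study_design <- function(n_horses = 12, n_re = 6, n_bs = 2,
                         image_height = 120, image_width = 160) {
  if (n_horses < 1 || n_re < 2 || n_bs != 2) {
    abort("invalid design: need n_horses >= 1, n_re >= 2, n_bs == 2")
  }
  if (image_height < 8 || image_width < 8) {
    abort("invalid design: non-positive or degenerate image dimensions")
  }
  structure(
    list(
      n_horses = as.integer(n_horses), n_re = as.integer(n_re),
      n_bs = as.integer(n_bs),
      image_height = as.integer(image_height),
      image_width = as.integer(image_width)
    ),
    class = "study_design"
  )
}

#' Reference biomarker panel parameters
#'
#' Per-biomarker generator parameters for the 12-parameter blood panel:
#' seven hematological (WBC, RBC, HGB, HCT, MCV, MCH, MCHC) and five
#' biochemical (LAC, TSP, CPK, ALT, AST) measures. `bs0_mean` is the resting
#' (BS 0) mean; `bs1_intercept` and the effect model's cumulative slope
#' define the post-exercise (BS 1) trend for the exercise-effect biomarkers
#' (WBC, CPK, AST); `acute_jump` is the within-repetition BS 1 elevation of
#' the acute markers (RBC, HGB, HCT, LAC); `sd_horse` / `sd_within` split the
#' dispersion into a between-horse offset and residual noise so that total
#' SDs approximate those reported for warmblood horses under standardized
#' exercise (e.g. post-exercise CPK ~200-300 +/- 50-100 U/L).
#'
#' @return A tibble with one row per biomarker.
#' @export
biomarker_reference <- function() {
  tibble::tribble(
    ~biomarker, ~unit,        ~bs0_mean, ~bs1_intercept, ~acute_jump, ~sd_horse, ~sd_within, ~floor,
    "WBC",      "1e9/L",      8.2,       7.56,           0,           1.1,       0.7,        0.01,
    "RBC",      "1e12/L",     8.6,       NA,             1.0,         0.7,       0.3,        0.01,
    "HGB",      "mmol/L",     8.7,       NA,             0.9,         0.7,       0.3,        0.01,
    "HCT",      "%",          38,        NA,             4.0,         3.0,       1.5,        0.01,
    "MCV",      "fL",         45,        NA,             0,           2.0,       1.0,        0.01,
    "MCH",      "pg",         15.5,      NA,             0,           1.0,       0.4,        0.01,
    "MCHC",     "mmol/L",     21,        NA,             0,           1.0,       0.5,        0.01,
    "LAC",      "mmol/L",     1.2,       NA,             4.5,         0.5,       0.8,        1.0,
    "TSP",      "g/L",        65,        NA,             0,           4.0,       2.0,        0.01,
    "CPK",      "U/L",        150,       183.6,          0,           55,        30,         0.01,
    "ALT",      "U/L",        10,        NA,             0,           3.0,       1.5,        0.01,
    "AST",      "U/L",        252,       223.8,          0,           40,        20,         0.01
  )
}

default_cumulative_slope <- function() {
  c(WBC = 0.44, CPK = 18.4, AST = 14.2, driver = 1)
}

#' Effect model for the synthetic study generator
#'
#' Parameterizes how exercise shows up in the synthetic data:
#'
#' * `re_warming` (degrees C) — uniform surface warming added at BS 1 over
#'   the withers and back-muscle regions (working muscle heat release);
#' * `cumulative_slope` — per-repetition linear increments at BS 1. A named
#'   vector with elements `WBC`, `CPK`, `AST` (each in that biomarker's
#'   units per RE) and `driver` (the dimensionless texture driver: the rate
#'   at which spatial temperature heterogeneity accumulates per RE). A
#'   scalar is recycled to all four. The biomarker slopes and the driver
#'   share the same per-RE linear trend up to independent noise — exactly
#'   the structure the slope-parallelism selection is meant to recover.
#' * `noise_sd` — a non-negative scale multiplying every Gaussian noise
#'   source (biomarker noise, pixel noise, latent driver noise); 0 makes the
#'   generator deterministic given the design;
#' * `acute_jump` — scale on the within-repetition BS 1 jumps of the acute
#'   markers (RBC, HGB, HCT, LAC); 1 uses the reference panel values;
#' * `coupled_biomarkers` — which of WBC/CPK/AST carry the cumulative trend.
#'
#' @param baseline_temp Resting skin surface temperature, degrees C.
#' @param re_warming Post-exercise warming over muscle regions, degrees C
#'   (>= 0).
#' @param cumulative_slope Named vector or scalar; see Details.
#' @param noise_sd Non-negative noise scale (1 = calibrated defaults).
#' @param acute_jump Scale on acute BS 1 biomarker jumps.
#' @param coupled_biomarkers Character subset of `c("WBC", "CPK", "AST")`.
#' @param biomarker_table Reference panel table; see [biomarker_reference()].
#' @return A list of class `effect_model`.
#' @examples
#' effect_model()                  # calibrated defaults
#' null_effect()                   # no exercise effect at all
#' effect_model(cumulative_slope = 0)  # no cumulative trends
#' @export
effect_model <- function(baseline_temp = 30, re_warming = 2,
                         cumulative_slope = default_cumulative_slope(),
                         noise_sd = 1, acute_jump = 1,
                         coupled_biomarkers = c("WBC", "CPK", "AST"),
                         biomarker_table = biomarker_reference()) {
  if (re_warming < 0) abort("re_warming must be >= 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  slope_names <- names(default_cumulative_slope())
  if (is.null(names(cumulative_slope))) {
    stopifnot(length(cumulative_slope) %in% c(1, 4))
    cumulative_slope <- setNames(
      rep_len(cumulative_slope, 4), slope_names
    )
  } else {
    stopifnot(all(names(cumulative_slope) %in% slope_names))
    full <- default_cumulative_slope()
    full[names(cumulative_slope)] <- cumulative_slope
    cumulative_slope <- full[slope_names]
  }
  stopifnot(all(coupled_biomarkers %in% c("WBC", "CPK", "AST")))
  structure(
    list(
      baseline_temp = baseline_temp, re_warming = re_warming,
      cumulative_slope = cumulative_slope, noise_sd = noise_sd,
      acute_jump = acute_jump, coupled_biomarkers = coupled_biomarkers,
      biomarker_table = biomarker_table,
      # latent driver noise (RE units): the latent spread (total ~2.8)
      # plus the intrinsic sampling noise of a region variance estimate
      # brings the feature series' residual-to-slope ratio to ~3.5 RE
      # units, matching the coupled biomarkers' (~3.4 for CPK)
      latent_sd_horse = 2.0, latent_sd_obs = 2.0,
      # heterogeneity sub-blobs: count per muscle region per latent RE unit,
      # absolute amplitude (random sign), and Gaussian footprint fraction
      blob_rate = 3, blob_amp = 1.5, blob_sigma_frac = 0.02,
      # baseline field texture
      horse_temp_sd = 0.4, gradient_amp = 0.8, pixel_noise_sd = 0.2
    ),
    class = "effect_model"
  )
}

#' @rdname effect_model
#' @export
null_effect <- function(baseline_temp = 30, noise_sd = 1) {
  effect_model(
    baseline_temp = baseline_temp, re_warming = 0, cumulative_slope = 0,
    noise_sd = noise_sd, acute_jump = 0
  )
}
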