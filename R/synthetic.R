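# Synthetic study generator: temperature fields, region masks, rendered
# thermograms and biomarker panels with the coupling structure the
# slope-parallelism selection is designed to recover.

#' Default thoracolumbar region masks
#'
#' Builds the four-region labeling used throughout: ROI 1 = withers (top
#' center), ROI 2 = thoracic spine (central vertical strip), ROI 3 / ROI 4 =
#' left / right back-muscle areas. Regions are axis-aligned ellipses placed
#' at fixed fractional positions, so the layout scales with the raster.
#'
#' @param height,width Raster dimensions in pixels.
#' @return An integer matrix with labels 0 (background) and 1-4.
#' @examples
#' table(default_roi_masks(60, 80))
#' @export
default_roi_masks <- function(height, width) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  ellipse <- function(cy, cx, ry, rx) {
    ((rr - cy * height) / (ry * height))^2 +
      ((cc - cx * width) / (rx * width))^2 <= 1
  }
  m <- matrix(0L, height, width)
  # order matters: later labels overwrite none because regions are disjoint
  # by construction; spine is drawn first and muscles carved beside it
  roi1 <- ellipse(0.30, 0.50, 0.13, 0.12)                  # withers
  roi2 <- ellipse(0.62, 0.50, 0.24, 0.055) & !roi1          # thoracic spine
  roi3 <- ellipse(0.62, 0.28, 0.21, 0.14) & !roi1 & !roi2  # left muscles
  roi4 <- ellipse(0.62, 0.72, 0.21, 0.14) & !roi1 & !roi2  # right muscles
  m[roi1] <- 1L; m[roi2] <- 2L; m[roi3] <- 3L; m[roi4] <- 4L
  m
}

# Logical mask list from a labeled raster.
roi_mask_list <- function(labels) {
  lapply(setNames(1:4, paste0("ROI", 1:4)), function(k) labels == k)
}

# Smooth unit-peak plateau over a region: Gaussian bump centered at the
# region centroid, scaled so warming covers the region without a hard edge.
roi_plateau <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  sy <- max(2, stats::sd(idx[, 1]) * 1.4)
  sx <- max(2, stats::sd(idx[, 2]) * 1.4)
  rr <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cc <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  exp(-0.5 * (((rr - cy) / sy)^2 + ((cc - cx) / sx)^2))
}

# Latent per-repetition heterogeneity level: re plus calibrated noise in RE
# units (between-horse offset supplied by the caller), truncated at 0.
latent_driver <- function(re, horse_latent, effect) {
  eps <- rnorm(1, 0, effect$latent_sd_obs * effect$noise_sd)
  max(0, re + horse_latent + eps)
}

#' Generate one synthetic surface temperature field
#'
#' Builds the per-pixel temperature grid (degrees C) for one thermogram:
#' a smooth baseline (resting temperature + per-horse offset + a gentle
#' fixed spatial gradient + pixel noise), and at BS 1 adds (i) uniform
#' warming of amplitude `re_warming` over the withers and back-muscle
#' regions and (ii) heterogeneity sub-blobs — small Gaussian patches with
#' random-sign amplitude (warm working-muscle spots, cool sweat patches)
#' whose count grows linearly with the latent repetition level, so the
#' spatial variance over muscle regions rises linearly across repetitions.
#' Values are clipped to the camera range 10.0-50.0 degrees C.
#'
#' @param design A [study_design()].
#' @param effect An [effect_model()].
#' @param horse,re,bs Indices: horse in `1..n_horses`, repetition in
#'   `1..n_re`, sampling time 0 (before) or 1 (after exercise).
#' @param horse_offsets Optional list of per-horse latent values (as drawn
#'   by [generate_study()]); when `NULL` they are drawn from the current RNG
#'   state.
#' @param masks Optional labeled mask raster; defaults to
#'   [default_roi_masks()].
#' @return A numeric matrix `image_height x image_width` (degrees C).
#' @export
generate_temperature_field <- function(design, effect, horse, re, bs,
                                       horse_offsets = NULL, masks = NULL) {
  check_indices(design, horse, re, bs)
  h <- design$image_height; w <- design$image_width
  masks <- masks %||% default_roi_masks(h, w)
  if (is.null(horse_offsets)) {
    horse_offsets <- list(
      temp = rnorm(1, 0, effect$horse_temp_sd * effect$noise_sd),
      latent = rnorm(1, 0, effect$latent_sd_horse * effect$noise_sd)
    )
  }
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  field <- effect$baseline_temp + horse_offsets$temp +
    effect$gradient_amp *
      (0.5 * cos(pi * (rr - h / 2) / h) + 0.5 * sin(pi * cc / w))
  if (effect$noise_sd > 0) {
    field <- field + matrix(
      rnorm(h * w, 0, effect$pixel_noise_sd * effect$noise_sd), h, w
    )
  }
  if (bs == 1) {
    muscle_rois <- c(1L, 3L, 4L)
    driver_slope <- effect$cumulative_slope[["driver"]]
    t_lat <- latent_driver(re, horse_offsets$latent, effect)
    sigma <- max(1.5, effect$blob_sigma_frac * min(h, w) + 1)
    # warming and heterogeneity are confined to their own region so the
    # spine (ROI 2) stays a clean uncoupled reference region
    for (k in muscle_rois) {
      mask <- masks == k
      if (!any(mask)) next
      bump <- matrix(0, h, w)
      if (effect$re_warming > 0) {
        bump <- bump + effect$re_warming * roi_plateau(mask)
      }
      n_blobs <- max(0L, as.integer(round(
        effect$blob_rate * driver_slope * t_lat
      )))
      if (n_blobs > 0) {
        centers <- which(mask)
        pick <- centers[sample.int(length(centers), n_blobs, replace = TRUE)]
        py <- (pick - 1L) %% h + 1L
        px <- (pick - 1L) %/% h + 1L
        signs <- sample(c(-1, 1), n_blobs, replace = TRUE)
        for (b in seq_len(n_blobs)) {
          bump <- bump + signs[b] * effect$blob_amp *
            exp(-0.5 * (((rr - py[b]) / sigma)^2 + ((cc - px[b]) / sigma)^2))
        }
      }
      field[mask] <- field[mask] + bump[mask]
    }
  }
  clamp(field, 10, 50)
}

check_indices <- function(design, horse, re, bs) {
  if (horse < 1 || horse > design$n_horses ||
      re < 1 || re > design$n_re || !(bs %in% c(0, 1))) {
    abort(sprintf(
      "out-of-range indices: horse=%s re=%s bs=%s for a %d x %d x 2 design",
      horse, re, bs, design$n_horses, design$n_re
    ))
  }
  invisible(TRUE)
}

#' Generate one biomarker panel row
#'
#' Draws the 12-parameter panel for one (horse, repetition, sampling time):
#' the exercise-effect biomarkers (WBC, CPK, AST, when coupled) follow
#' `bs1_intercept + cumulative_slope * re` at BS 1; the acute markers (RBC,
#' HGB, HCT, LAC) are elevated at BS 1 within every repetition but carry no
#' across-repetition trend; the remainder fluctuate around their resting
#' means. All values are positive; LAC is floored at the 1.0 mmol/L
#' detection limit.
#'
#' @inheritParams generate_temperature_field
#' @param horse_offsets Optional named numeric vector of per-horse biomarker
#'   offsets (one per panel parameter).
#' @return A one-row tibble with columns `horse`, `re`, `bs` and the 12
#'   panel parameters.
#' @export
generate_biomarker_panel <- function(design, effect, horse, re, bs,
                                     horse_offsets = NULL) {
  check_indices(design, horse, re, bs)
  tab <- effect$biomarker_table
  if (is.null(horse_offsets)) {
    horse_offsets <- setNames(
      rnorm(nrow(tab), 0, tab$sd_horse * effect$noise_sd), tab$biomarker
    )
  }
  vals <- vapply(seq_len(nrow(tab)), function(i) {
    b <- tab$biomarker[i]
    coupled <- bs == 1 && b %in% effect$coupled_biomarkers &&
      b %in% names(effect$cumulative_slope)
    mu <- if (coupled) {
      # acute post-exercise shift (bs1_intercept - bs0_mean, scaled like
      # the other acute jumps) plus the cumulative per-repetition trend
      tab$bs0_mean[i] +
        effect$acute_jump * (tab$bs1_intercept[i] - tab$bs0_mean[i]) +
        effect$cumulative_slope[[b]] * re
    } else if (bs == 1) {
      tab$bs0_mean[i] + effect$acute_jump * tab$acute_jump[i]
    } else {
      tab$bs0_mean[i]
    }
    x <- mu + horse_offsets[[b]] +
      rnorm(1, 0, tab$sd_within[i] * effect$noise_sd)
    max(x, tab$floor[i])
  }, numeric(1))
  tibble::as_tibble(c(
    list(horse = as.integer(horse), re = as.integer(re), bs = as.integer(bs)),
    setNames(as.list(vals), tab$biomarker)
  ))
}

#' Generate a full synthetic study bundle
#'
#' Produces the complete study the analysis pipeline expects: for every
#' (horse, repetition, sampling time) cell a temperature field, its rendered
#' rainbow-palette thermogram, shared region masks, and a biomarker row. The
#' default design yields 144 thermograms (12 horses x 6 repetitions x 2
#' sampling times). Output is bit-identical for a fixed `seed`.
#'
#' @param design A [study_design()].
#' @param effect An [effect_model()].
#' @param seed Integer RNG seed.
#' @param palette Palette used to render thermograms.
#' @param render_range Temperature range mapped onto the palette. The
#'   default `c(15, 55)` places the physiological skin range (roughly 28-35
#'   degrees C) on the green-to-yellow ramp of the palette, where the red
#'   channel responds linearly to temperature (the camera measurement range
#'   stays 10-50).
#' @return A list of class `irt_study` with elements `images` (tibble with
#'   columns `horse`, `re`, `bs` and list-columns `field`, `image`), `masks`
#'   (labeled raster), `biomarkers` (tibble), plus `design`, `effect`,
#'   `palette`, `render_range`, `seed`.
#' @examples
#' study <- generate_study(study_design(n_horses = 1, n_re = 2,
#'                                      image_height = 40, image_width = 48),
#'                         effect_model(), seed = 1)
#' nrow(study$images)  # 1 x 2 x 2 = 4 thermograms
#' @export
generate_study <- function(design, effect, seed = 1,
                           palette = rainbow_palette(),
                           render_range = c(15, 55)) {
  stopifnot(inherits(design, "study_design"), inherits(effect, "effect_model"))
  set.seed(as.integer(seed))
  h <- design$image_height; w <- design$image_width
  masks <- default_roi_masks(h, w)
  tab <- effect$biomarker_table

  grid <- tidyr::expand_grid(
    horse = seq_len(design$n_horses),
    re = seq_len(design$n_re),
    bs = 0:1
  )
  # per-horse latent offsets drawn once, shared by both sampling times
  horse_draws <- lapply(seq_len(design$n_horses), function(i) {
    list(
      temp = rnorm(1, 0, effect$horse_temp_sd * effect$noise_sd),
      latent = rnorm(1, 0, effect$latent_sd_horse * effect$noise_sd),
      biomarkers = setNames(
        rnorm(nrow(tab), 0, tab$sd_horse * effect$noise_sd), tab$biomarker
      )
    )
  })

  rows <- purrr::pmap(grid, function(horse, re, bs) {
    off <- horse_draws[[horse]]
    field <- generate_temperature_field(
      design, effect, horse, re, bs,
      horse_offsets = off[c("temp", "latent")], masks = masks
    )
    image <- temperature_to_rgb(field, palette, render_range)
    bio <- generate_biomarker_panel(
      design, effect, horse, re, bs, horse_offsets = off$biomarkers
    )
    list(field = field, image = image, bio = bio)
  })

  images <- dplyr::mutate(
    grid,
    field = purrr::map(rows, "field"),
    image = purrr::map(rows, "image")
  )
  structure(
    list(
      images = images,
      masks = masks,
      biomarkers = dplyr::bind_rows(purrr::map(rows, "bio")),
      design = design, effect = effect, palette = palette,
      render_range = render_range, seed = as.integer(seed)
    ),
    class = "irt_study"
  )
}

#' @export
print.irt_study <- function(x, ...) {
  cat(sprintf(
    "<irt_study> %d horses x %d RE x 2 BS = %d thermograms (%d x %d px)\n",
    x$design$n_horses, x$design$n_re, nrow(x$images),
    x$design$image_height, x$design$image_width
  ))
  cat(sprintf(
    "  regions: %s\n",
    paste(sprintf("ROI%d=%dpx", 1:4, tabulate(x$masks, 4)), collapse = " ")
  ))
  cat(sprintf("  biomarkers: %d rows x %d parameters\n",
              nrow(x$biomarkers), ncol(x$biomarkers) - 3L))
  invisible(x)
}
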