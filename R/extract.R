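# Feature-extraction orchestration: 88 features x 24 channel variants x 4
# regions per thermogram, plus conventional temperature measures.

#' Canonical texture feature names
#'
#' The 88 feature names grouped by family: HS (14), GM (6), AM (5), GT
#' (24), HOG (8), GRLM (7), GLCM (12), GLCH (12). Names are the bare
#' per-family names; the feature-table identifier is `<family>.<name>`
#' (e.g. `HS.Variance`, `GLCH.SumOfSqs`), which together with the channel
#' letter reproduces the conventional `R.HS.Variance` labels.
#'
#' @return Named list of character vectors.
#' @export
feature_names <- function() {
  haralick <- c(
    "Area", "AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDefMom",
    "SumAverg", "SumEntrp", "SumVarnc", "Entropy", "DifVarnc", "DifEntrp"
  )
  list(
    HS = c(
      "Area", "Mean", "Variance", "Skewness", "Kurtosis",
      "Perc01", "Perc10", "Perc50", "Perc90", "Perc99",
      "Domn01", "Domn10", "Maxm01", "Maxm10"
    ),
    GM = c("Area", "Mean", "Variance", "Skewness", "Kurtosis", "NonZeros"),
    AM = c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma"),
    GT = as.vector(t(outer(
      .gabor_lambdas, names(.gabor_orientations),
      function(l, o) sprintf("Gab%d%s%dMag", l, o, l / 2)
    ))),
    HOG = paste0("O8b", 0:7),
    GRLM = c(
      "RLNonUni", "GLevNonUn", "LngREmph", "ShrtREmp", "Fraction",
      "MRLNonUni", "MGLevNonUn"
    ),
    GLCM = haralick,
    GLCH = haralick
  )
}

# Compute one family on one channel variant, returning the full named
# vector; a family failure (e.g. region too thin) yields all-NA with a
# single warning, never a partial vector.
family_features <- function(family, values, roi, config) {
  expected <- feature_names()[[family]]
  res <- tryCatch(
    switch(family,
      HS = hist_features(values, roi, n_levels = 2^config$color$bit_depth),
      GM = gradient_features(values, roi),
      AM = ar_features(values, roi),
      GT = gabor_features(values, roi),
      HOG = hog_features(values, roi),
      GRLM = glrlm_features(
        requantize(values, config$color$bit_depth, config$color$glcm_bit_depth),
        roi, n_levels = 2^config$color$glcm_bit_depth
      ),
      GLCM = glcm_features(
        requantize(values, config$color$bit_depth, config$color$glcm_bit_depth),
        roi, config = config$glcm,
        n_levels = 2^config$color$glcm_bit_depth, symmetric = TRUE
      ),
      GLCH = glcm_features(
        requantize(values, config$color$bit_depth, config$color$glcm_bit_depth),
        roi, config = config$glcm,
        n_levels = 2^config$color$glcm_bit_depth, symmetric = FALSE
      )
    ),
    error = function(e) {
      warn(sprintf("family %s unavailable: %s", family, conditionMessage(e)))
      setNames(rep(NA_real_, length(expected)), expected)
    }
  )
  res[expected]
}

#' Extract all texture features from one thermogram
#'
#' Runs the eight texture approaches on every channel variant of every
#' region: 88 features x 24 channel variants x 4 regions = 8448 rows per
#' image (2112 combinations per region). When a temperature field is
#' supplied, conventional `Tmax` / `Taver` rows (channel `IRT`) are
#' appended.
#'
#' @param image Integer array `h x w x 3` (8-bit RGB thermogram).
#' @param masks Labeled mask raster (values 0-4).
#' @param config A [pipeline_config()] (only the `color`, `glcm` and
#'   `texture` sections are used).
#' @param field Optional temperature field for the conventional measures.
#' @return A tibble with columns `roi`, `model`, `channel`,
#'   `normalization`, `feature`, `value`.
#' @export
extract_image_features <- function(image, masks, config = pipeline_config(),
                                   field = NULL) {
  families <- config$texture$families
  rois <- roi_mask_list(masks)
  planes <- decompose_channels(image)
  row_chunk <- function(roi, model, channel, normalization, feature, value) {
    n <- length(value)
    tibble::new_tibble(list(
      roi = rep.int(roi, n), model = rep.int(model, n),
      channel = rep.int(channel, n),
      normalization = rep.int(normalization, n),
      feature = feature, value = unname(value)
    ), nrow = n)
  }
  out <- vector("list", 0)
  for (k in seq_along(rois)) {
    roi <- rois[[k]]
    if (!any(roi)) abort(sprintf("empty mask for ROI %d", k))
    variants <- channel_variants(
      image, roi,
      normalization = config$color$normalization,
      bit_depth = config$color$bit_depth,
      channels = config$texture$channels,
      planes = planes
    )
    for (v in seq_len(nrow(variants))) {
      values <- variants$values[[v]]
      for (fam in families) {
        f <- family_features(fam, values, roi, config)
        out[[length(out) + 1L]] <- row_chunk(
          k, variants$model[v], variants$channel[v],
          variants$normalization[v], paste(fam, names(f), sep = "."), f
        )
      }
    }
    if (!is.null(field)) {
      tt <- roi_temperatures(field, masks)
      out[[length(out) + 1L]] <- row_chunk(
        k, "IRT", "IRT", "none", c("Tmax", "Taver"),
        c(tt$Tmax[k], tt$Taver[k])
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Extract the feature table for a whole study
#'
#' Applies [extract_image_features()] to every thermogram of a study bundle
#' and returns the long-format feature table (one row per horse x
#' repetition x sampling time x region x channel variant x feature).
#'
#' @param study An `irt_study` (see [generate_study()] / [read_study()]).
#' @param config A [pipeline_config()].
#' @param conventional Append the conventional `Tmax` / `Taver` rows
#'   (default `TRUE`). Temperatures come from the stored float field when
#'   present, else from palette inversion of the rendered thermogram.
#' @return A tibble with columns `horse`, `re`, `bs`, `roi`, `model`,
#'   `channel`, `normalization`, `feature`, `value`.
#' @export
extract_features <- function(study, config = pipeline_config(),
                             conventional = TRUE) {
  stopifnot(inherits(study, "irt_study"))
  rows <- purrr::pmap(
    study$images,
    function(horse, re, bs, field, image) {
      fld <- if (!conventional) NULL else if (!is.null(field)) field else
        rgb_to_temperature(image, study$palette, study$render_range)
      dplyr::mutate(
        extract_image_features(image, study$masks, config, field = fld),
        horse = horse, re = re, bs = bs, .before = 1
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Conventional thermography measures per region
#'
#' `Tmax` is the maximal and `Taver` the arithmetic mean temperature over
#' each region of the temperature field.
#'
#' @param field Numeric temperature matrix (degrees C).
#' @param masks Labeled mask raster with regions 1-4.
#' @return A tibble with columns `roi`, `Tmax`, `Taver`.
#' @export
roi_temperatures <- function(field, masks) {
  stopifnot(all(dim(field) == dim(masks)))
  rois <- roi_mask_list(masks)
  empty <- !vapply(rois, any, logical(1))
  if (any(empty)) {
    abort(paste("empty mask for ROI", which(empty)[1]))
  }
  tibble::tibble(
    roi = seq_along(rois),
    Tmax = unname(vapply(rois, function(m) max(field[m]), numeric(1))),
    Taver = unname(vapply(rois, function(m) mean(field[m]), numeric(1)))
  )
}
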