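# Reading and writing study bundles and tables.
#
# Layout of a study directory:
#   images/h<horse>_re<re>_bs<bs>.png   8-bit RGB thermograms
#   fields/h<horse>_re<re>_bs<bs>.tif   32-bit float temperature (deg C)
#   masks.png                           labeled regions {0..4}
#   biomarkers.csv                      horse,re,bs,<12 parameters>
#   study.yaml                          design / palette / render range

study_stem <- function(horse, re, bs) sprintf("h%02d_re%d_bs%d", horse, re, bs)

# Temperatures are stored as native 32-bit float samples; the tiff writer
# clamps to [0, 1], so fields are scaled by the camera range [10, 50].
.temp_range <- c(10, 50)

write_field_tiff <- function(field, path) {
  scaled <- (field - .temp_range[1]) / diff(.temp_range)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32, reduce = FALSE)
}

read_field_tiff <- function(path) {
  scaled <- tiff::readTIFF(path)
  scaled * diff(.temp_range) + .temp_range[1]
}

#' Write a study bundle to disk
#'
#' Serializes an `irt_study` into plain rasters and tables: PNG thermograms
#' and label masks, float-TIFF temperature fields, a biomarker CSV and a
#' YAML metadata file. Writes are deterministic byte streams for a fixed
#' study.
#'
#' @param study An `irt_study`.
#' @param dir Output directory (created if missing).
#' @param fields Also write the temperature fields (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, fields = TRUE) {
  stopifnot(inherits(study, "irt_study"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (fields) {
    dir.create(file.path(dir, "fields"), recursive = TRUE, showWarnings = FALSE)
  }
  purrr::pwalk(study$images, function(horse, re, bs, field, image) {
    stem <- study_stem(horse, re, bs)
    png::writePNG(image / 255, file.path(dir, "images", paste0(stem, ".png")))
    if (fields) {
      write_field_tiff(field, file.path(dir, "fields", paste0(stem, ".tif")))
    }
  })
  png::writePNG(study$masks / 255, file.path(dir, "masks.png"))
  readr::write_csv(study$biomarkers, file.path(dir, "biomarkers.csv"))
  yaml::write_yaml(
    list(
      design = unclass(study$design),
      render_range = study$render_range,
      palette = as.data.frame(study$palette),
      seed = study$seed
    ),
    file.path(dir, "study.yaml")
  )
  invisible(dir)
}

#' Read a study bundle from disk
#'
#' Inverse of [write_study()]: reads thermograms, masks, optional
#' temperature fields and the biomarker table, validating dimensions and
#' mask labels. Thermograms are read as plain 8-bit RGB without palette
#' assumptions; real (camera-exported) image folders with the same layout
#' load the same way.
#'
#' @param dir Study directory.
#' @return An `irt_study`.
#' @export
read_study <- function(dir) {
  meta_path <- file.path(dir, "study.yaml")
  if (!file.exists(meta_path)) abort(paste("missing file:", meta_path))
  meta <- yaml::read_yaml(meta_path)
  design <- do.call(study_design, meta$design[
    c("n_horses", "n_re", "n_bs", "image_height", "image_width")
  ])
  mask_path <- file.path(dir, "masks.png")
  if (!file.exists(mask_path)) abort(paste("missing file:", mask_path))
  masks <- round(png::readPNG(mask_path) * 255)
  storage.mode(masks) <- "integer"
  bad <- setdiff(unique(as.vector(masks)), 0:4)
  if (length(bad)) {
    abort(sprintf("mask %s contains invalid label(s): %s",
                  mask_path, paste(bad, collapse = ", ")))
  }
  bio_path <- file.path(dir, "biomarkers.csv")
  if (!file.exists(bio_path)) abort(paste("missing file:", bio_path))
  biomarkers <- readr::read_csv(bio_path, show_col_types = FALSE)

  grid <- tidyr::expand_grid(
    horse = seq_len(design$n_horses), re = seq_len(design$n_re), bs = 0:1
  )
  load_one <- function(horse, re, bs) {
    stem <- study_stem(horse, re, bs)
    ipath <- file.path(dir, "images", paste0(stem, ".png"))
    if (!file.exists(ipath)) abort(paste("missing file:", ipath))
    arr <- png::readPNG(ipath)
    if (length(dim(arr)) == 3 && dim(arr)[3] == 4) arr <- arr[, , 1:3]
    image <- array(as.integer(round(arr * 255)), dim = dim(arr))
    if (!all(dim(image)[1:2] == dim(masks))) {
      abort(sprintf("dimension mismatch between %s and %s", ipath, mask_path))
    }
    fpath <- file.path(dir, "fields", paste0(stem, ".tif"))
    field <- if (file.exists(fpath)) read_field_tiff(fpath) else NULL
    list(field = field, image = image)
  }
  rows <- purrr::pmap(grid, load_one)
  images <- dplyr::mutate(
    grid,
    field = purrr::map(rows, "field"),
    image = purrr::map(rows, "image")
  )
  palette <- if (!is.null(meta$palette)) {
    rainbow_palette(tibble::as_tibble(
      purrr::map(meta$palette, unlist)
    ))
  } else rainbow_palette()
  structure(
    list(
      images = images, masks = masks, biomarkers = biomarkers,
      design = design, effect = NULL, palette = palette,
      render_range = unlist(meta$render_range), seed = meta$seed
    ),
    class = "irt_study"
  )
}

#' Write / read a long-format feature table
#'
#' CSV round trip for the feature table produced by [extract_features()].
#'
#' @param table Feature tibble.
#' @param path CSV path.
#' @return The path (write) or the tibble (read).
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste("missing file:", path))
  readr::read_csv(
    path,
    col_types = readr::cols(
      horse = "i", re = "i", bs = "i", roi = "i",
      model = "c", channel = "c", normalization = "c", feature = "c",
      value = "d"
    )
  )
}
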