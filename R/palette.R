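#' Rainbow palettes for pseudo-color thermogram rendering
#'
#' Thermal cameras render surface temperature with a monotone "rainbow"
#' palette: the cold end is blue-dominant, the hot end red-dominant. A
#' palette is a set of control points (temperature fraction in `[0, 1]`,
#' 8-bit RGB triple) interpolated linearly per channel.
#'
#' Two built-in variants are provided:
#' * `"rainbow7"` (default): blue, cyan, green, yellow, orange, red, white;
#' * `"magenta8"`: the same with a magenta stop between red and white, for
#'   conventions that annotate medium-high temperatures in magenta.
#'
#' @param variant Palette name, `"rainbow7"` or `"magenta8"`, or a tibble
#'   with columns `frac`, `r`, `g`, `b` (frac strictly increasing from 0 to
#'   1; channels in 0..255) to define a custom palette.
#' @return A tibble of class `rainbow_palette` with columns `frac`, `r`,
#'   `g`, `b`.
#' @examples
#' pal <- rainbow_palette()
#' field <- matrix(seq(20, 40, length.out = 12), 3, 4)
#' img <- temperature_to_rgb(field, pal, range = c(10, 50))
#' @export
rainbow_palette <- function(variant = c("rainbow7", "magenta8")) {
  if (is.data.frame(variant)) {
    pal <- tibble::as_tibble(variant)
    stopifnot(all(c("frac", "r", "g", "b") %in% names(pal)))
  } else {
    variant <- match.arg(variant)
    stops <- switch(variant,
      rainbow7 = list(
        c(0, 0, 255), c(0, 255, 255), c(0, 255, 0), c(255, 255, 0),
        c(255, 165, 0), c(255, 0, 0), c(255, 255, 255)
      ),
      magenta8 = list(
        c(0, 0, 255), c(0, 255, 255), c(0, 255, 0), c(255, 255, 0),
        c(255, 165, 0), c(255, 0, 0), c(255, 0, 255), c(255, 255, 255)
      )
    )
    m <- do.call(rbind, stops)
    pal <- tibble::tibble(
      frac = seq(0, 1, length.out = nrow(m)),
      r = m[, 1], g = m[, 2], b = m[, 3]
    )
  }
  if (is.unsorted(pal$frac, strictly = TRUE) || pal$frac[1] != 0 ||
      pal$frac[nrow(pal)] != 1) {
    abort("palette control fractions must increase strictly from 0 to 1")
  }
  class(pal) <- c("rainbow_palette", class(pal))
  pal
}

# Interpolate the palette at fractions in [0, 1]; returns a matrix with
# columns r, g, b (continuous, un-rounded).
palette_interpolate <- function(palette, frac) {
  sapply(c("r", "g", "b"), function(ch) {
    stats::approx(palette$frac, palette[[ch]], xout = frac, rule = 2)$y
  })
}

#' Render a temperature field as an 8-bit RGB thermogram
#'
#' Maps each pixel's temperature linearly onto the palette position within
#' `range` (values outside are clipped to the endpoints), then interpolates
#' the palette to an 8-bit RGB triple.
#'
#' @param field Numeric matrix of temperatures (degrees C).
#' @param palette A [rainbow_palette()].
#' @param range Length-2 numeric, `c(tmin, tmax)` with `tmin < tmax`.
#' @return An integer array `h x w x 3` with values in 0..255.
#' @seealso [rgb_to_temperature()] for the inverse lookup.
#' @export
temperature_to_rgb <- function(field, palette = rainbow_palette(),
                               range = c(10, 50)) {
  stopifnot(is.matrix(field), length(range) == 2)
  if (!(range[1] < range[2])) {
    abort("degenerate render range: tmin must be < tmax")
  }
  frac <- clamp((field - range[1]) / (range[2] - range[1]), 0, 1)
  rgb <- palette_interpolate(palette, as.vector(frac))
  out <- array(0L, c(nrow(field), ncol(field), 3))
  for (k in 1:3) {
    out[, , k] <- as.integer(clamp(round_half_up(rgb[, k]), 0, 255))
  }
  out
}

# Densely sampled palette curve used for nearest-point inversion.
palette_curve <- function(palette, m = 2048L) {
  frac <- seq(0, 1, length.out = m)
  list(frac = frac, rgb = palette_interpolate(palette, frac))
}

#' Recover a temperature field from a rendered thermogram
#'
#' Inverse of [temperature_to_rgb()]: each pixel's RGB triple is snapped to
#' the nearest point (squared Euclidean distance in RGB space) on a densely
#' sampled palette curve, and the curve position is mapped back to a
#' temperature within `range`. Colors off the palette curve (e.g. overlaid
#' annotations) snap to the nearest curve point rather than failing.
#'
#' @param image Integer array `h x w x 3` rendered with the same palette
#'   and range.
#' @inheritParams temperature_to_rgb
#' @param samples Number of curve samples for the inverse lookup.
#' @return Numeric matrix of temperatures (degrees C).
#' @export
rgb_to_temperature <- function(image, palette = rainbow_palette(),
                               range = c(10, 50), samples = 2048L) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (!(range[1] < range[2])) {
    abort("degenerate render range: tmin must be < tmax")
  }
  curve <- palette_curve(palette, samples)
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  # nearest curve point: argmin_j ||p - c_j||^2 = argmin_j (||c_j||^2 - 2 p.c_j)
  cc <- rowSums(curve$rgb^2)
  # chunk the pixel set to bound the distance-matrix size
  idx <- integer(nrow(px))
  step <- 20000L
  for (s in seq(1, nrow(px), by = step)) {
    e <- min(s + step - 1L, nrow(px))
    d <- matrix(cc, e - s + 1L, length(cc), byrow = TRUE) -
      2 * px[s:e, , drop = FALSE] %*% t(curve$rgb)
    idx[s:e] <- max.col(-d, ties.method = "first")
  }
  matrix(range[1] + curve$frac[idx] * (range[2] - range[1]), h, w)
}
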