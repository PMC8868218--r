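# Color-model decomposition and gray-level normalization.
#
# A thermogram is decomposed into the 12 components of the RGB, YUV, YIQ and
# HSB color models (Y appears in both YUV and YIQ; B denotes blue in RGB and
# brightness in HSB). Each raw component plane is an un-quantized gray plane
# on the 8-bit range [0, 255]; normalization maps it onto integer gray
# levels [1, 2^n].

# BT.601 luma weights and the standard chrominance half-ranges (for RGB in
# [0, 255]): the achromatic value of each signed chrominance plane is mapped
# to the center of the gray range.
.luma <- c(r = 0.299, g = 0.587, b = 0.114)
.chroma_max <- c(
  U = 0.492 * (1 - 0.114) * 255,  # max |0.492 (B - Y)|
  V = 0.877 * (1 - 0.299) * 255,  # max |0.877 (R - Y)|
  I = 0.596 * 255,                # max |0.596 R - 0.274 G - 0.322 B|
  Q = 0.523 * 255                 # max |0.211 R - 0.523 G + 0.312 B|
)

#' Decompose a thermogram into the 12 color-model components
#'
#' Computes the raw gray planes for the RGB (R, G, B), YUV (Y, U, V), YIQ
#' (Y, I, Q) and HSB (H, S, B) color models. RGB planes pass through; Y uses
#' the BT.601 luma weights; the signed chrominance planes (U, V, I, Q) are
#' mapped affinely so the achromatic value lands at the center of the 8-bit
#' gray range; hue is linearized from `[0, 360)` degrees onto the gray
#' range; saturation (hexcone model, in `[0, 1]`) and brightness
#' (`max(R, G, B)`) likewise. Every returned plane is a real-valued matrix
#' on `[0, 255]`.
#'
#' @param image Integer array `h x w x 3` (8-bit RGB).
#' @return A tibble with columns `model` (RGB/YUV/YIQ/HSB), `channel`
#'   (component letter) and the list-column `plane`; exactly 12 rows.
#' @examples
#' img <- array(128L, c(4, 4, 3))
#' decompose_channels(img)
#' @export
decompose_channels <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  R <- matrix(as.numeric(image[, , 1]), h, w)
  G <- matrix(as.numeric(image[, , 2]), h, w)
  B <- matrix(as.numeric(image[, , 3]), h, w)
  Y <- .luma["r"] * R + .luma["g"] * G + .luma["b"] * B
  chroma <- function(x, key) 127.5 * (1 + x / .chroma_max[[key]])
  U <- chroma(0.492 * (B - Y), "U")
  V <- chroma(0.877 * (R - Y), "V")
  I <- chroma(0.596 * R - 0.274 * G - 0.322 * B, "I")
  Q <- chroma(0.211 * R - 0.523 * G + 0.312 * B, "Q")
  mx <- pmax(R, G, B); mn <- pmin(R, G, B); d <- mx - mn
  S <- ifelse(mx > 0, d / mx, 0) * 255
  # hexcone hue in degrees, 0 for achromatic pixels
  Hdeg <- matrix(0, nrow(R), ncol(R))
  ch <- d > 0
  hr <- ch & mx == R; Hdeg[hr] <- ((G - B)[hr] / d[hr]) %% 6
  hg <- ch & mx == G & !hr; Hdeg[hg] <- (B - R)[hg] / d[hg] + 2
  hb <- ch & mx == B & !hr & !hg; Hdeg[hb] <- (R - G)[hb] / d[hb] + 4
  Hdeg <- Hdeg * 60
  H <- Hdeg * 255 / 360
  tibble::tibble(
    model = rep(c("RGB", "YUV", "YIQ", "HSB"), each = 3),
    channel = c("R", "G", "B", "Y", "U", "V", "Y", "I", "Q", "H", "S", "B"),
    plane = list(R, G, B, Y, U, V, Y, I, Q, H, S, mx)
  )
}

#' Normalization scheme for gray-level channels
#'
#' Defines how a raw gray plane is mapped onto integer levels `[1, 2^n]`.
#' The bounds `MIN`/`MAX` are derived from the pixels of the region of
#' interest only:
#'
#' * `none` — no rescaling; gray levels are rounded and shifted onto
#'   `[1, 2^n]`;
#' * `mu3sigma` — `MIN = mu - 3 sigma`, `MAX = mu + 3 sigma` (gray-level
#'   mean and SD over the region);
#' * `minmax` — region minimum and maximum;
#' * `perc1_99` — 1st and 99th histogram percentiles (smallest gray level
#'   whose empirical CDF reaches the quantile).
#'
#' @param kind One of `"none"`, `"mu3sigma"`, `"minmax"`, `"perc1_99"`.
#' @param n Output bit depth (levels `1..2^n`).
#' @return A list of class `norm_scheme`.
#' @export
norm_scheme <- function(kind = c("none", "mu3sigma", "minmax", "perc1_99"),
                        n = 8) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n = as.integer(n)), class = "norm_scheme")
}

# Derive (MIN, MAX) bounds from region pixels.
norm_bounds <- function(x, kind) {
  switch(kind,
    none = c(NA_real_, NA_real_),
    mu3sigma = {
      mu <- mean(x); sig <- sqrt(mean((x - mu)^2))
      c(mu - 3 * sig, mu + 3 * sig)
    },
    minmax = range(x),
    perc1_99 = {
      xs <- sort(x)
      cdf <- seq_along(xs) / length(xs)
      c(xs[which(cdf >= 0.01 - 1e-12)[1]], xs[which(cdf >= 0.99 - 1e-12)[1]])
    }
  )
}

#' Normalize a gray plane onto integer levels `[1, 2^n]`
#'
#' Applies the gray-level normalization
#' `I_OUT = clamp(round(2^n * (I_IN - MIN) / (MAX - MIN)) + 1, 1, 2^n)`
#' with round-half-up, after clipping input to `[MIN, MAX]`. Bounds are
#' derived from the region pixels only (see [norm_scheme()]); the mapping is
#' applied to the whole plane so downstream neighborhoods stay defined.
#' `kind = "none"` rounds and shifts to `[1, 2^n]` without rescaling.
#'
#' A constant plane under a data-driven scheme has `MAX == MIN`; the result
#' is then the all-1 plane, flagged with attribute `degenerate = TRUE`.
#'
#' @param plane Numeric matrix on `[0, 255]` (a raw component plane).
#' @param scheme A [norm_scheme()].
#' @param roi Logical matrix: the region from which bounds are derived.
#' @return Integer matrix with values in `[1, 2^n]`, attributes `bit_depth`
#'   and (when applicable) `degenerate`.
#' @export
normalize_plane <- function(plane, scheme = norm_scheme("minmax"), roi) {
  stopifnot(is.matrix(plane), is.matrix(roi), all(dim(plane) == dim(roi)))
  if (!any(roi)) abort("empty region of interest")
  n <- scheme$n
  top <- 2^n
  if (scheme$kind == "none") {
    out <- clamp(round_half_up(plane) + 1, 1, 256)
  } else {
    b <- norm_bounds(plane[roi], scheme$kind)
    if (!(b[1] < b[2])) {
      out <- matrix(1, nrow(plane), ncol(plane))
      storage.mode(out) <- "integer"
      attr(out, "bit_depth") <- n
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    x <- clamp(plane, b[1], b[2])
    out <- clamp(round_half_up(top * (x - b[1]) / (b[2] - b[1])) + 1, 1, top)
  }
  storage.mode(out) <- "integer"
  attr(out, "bit_depth") <- n
  out
}

#' Enumerate the 24 channel variants of a thermogram for one region
#'
#' For each of the 12 color components, produces the un-normalized variant
#' (capital channel letter, scheme `none`) and one normalized variant
#' (lowercase letter, scheme `normalization`), i.e. 24 channel variants —
#' the gray images on which the 88 texture features are computed (88 x 24 =
#' 2112 combinations per region).
#'
#' @param image Integer array `h x w x 3` (8-bit RGB thermogram).
#' @param roi Logical matrix; normalization bounds are derived from these
#'   pixels.
#' @param normalization Kind of the normalized variant (default `minmax`).
#' @param bit_depth Bit depth of the channel images (default 8).
#' @param channels Optional character subset of component letters (e.g.
#'   `"R"`) to restrict the enumeration.
#' @param planes Optional precomputed [decompose_channels()] result (the
#'   decomposition is region-independent, so callers iterating regions can
#'   share it).
#' @return A tibble with columns `model`, `channel` (lowercase when
#'   normalized), `normalization`, and list-column `values` (integer gray
#'   matrices in `[1, 2^bit_depth]`).
#' @export
channel_variants <- function(image, roi, normalization = "minmax",
                             bit_depth = 8, channels = NULL, planes = NULL) {
  planes <- planes %||% decompose_channels(image)
  if (!is.null(channels)) {
    planes <- planes[planes$channel %in% channels, ]
  }
  none <- norm_scheme("none", bit_depth)
  norm <- norm_scheme(normalization, bit_depth)
  n <- nrow(planes)
  tibble::new_tibble(
    list(
      model = rep(planes$model, 2),
      channel = c(planes$channel, tolower(planes$channel)),
      normalization = rep(c("none", normalization), each = n),
      values = c(
        lapply(planes$plane, normalize_plane, scheme = none, roi = roi),
        lapply(planes$plane, normalize_plane, scheme = norm, roi = roi)
      )
    ),
    nrow = 2L * n
  )
}
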