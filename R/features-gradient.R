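# Gradient magnitude on the region interior, shared by the gradient-map and
# HOG families. Central differences are defined on the 4-neighborhood
# erosion of the region (every N/S/E/W neighbor inside the region and the
# image), so no out-of-region pixel leaks into a derivative.
roi_gradient <- function(values, roi) {
  h <- nrow(values); w <- ncol(values)
  inner <- erode4(roi)
  if (!any(inner)) abort("region too thin: no interior for central differences")
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  idx <- which(inner, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  gx[inner] <- (values[cbind(r, c + 1L)] - values[cbind(r, c - 1L)]) / 2
  gy[inner] <- (values[cbind(r + 1L, c)] - values[cbind(r - 1L, c)]) / 2
  list(
    interior = inner,
    gx = gx[inner], gy = gy[inner],
    mag = sqrt(gx[inner]^2 + gy[inner]^2)
  )
}

#' Gradient map (GM) features
#'
#' Statistics of the absolute brightness gradient over the region interior.
#' The gradient magnitude is `sqrt(Gx^2 + Gy^2)` with central differences in
#' the horizontal and vertical directions, defined on the 1-pixel erosion of
#' the region. Six features: interior area, population mean / variance /
#' skewness / kurtosis of the magnitude, and the fraction of interior pixels
#' with non-zero magnitude.
#'
#' @inheritParams hist_features
#' @return Named numeric vector of 6 features (`Area`, `Mean`, `Variance`,
#'   `Skewness`, `Kurtosis`, `NonZeros`).
#' @export
gradient_features <- function(values, roi) {
  g <- roi_gradient(values, roi)
  mom <- dist_moments(g$mag)
  c(Area = sum(g$interior), mom, NonZeros = mean(g$mag > 0))
}

#' Histogram of oriented gradients (HOG) features
#'
#' Magnitude-weighted histogram of unsigned gradient orientations over the
#' region interior. Orientations in `[0, 180)` degrees are binned into 8
#' bins of 22.5 degrees; the histogram is normalized to sum 1 (a region with
#' no gradient anywhere yields the all-zero vector).
#'
#' @inheritParams hist_features
#' @return Named numeric vector of 8 features (`O8b0` ... `O8b7`).
#' @export
hog_features <- function(values, roi) {
  g <- roi_gradient(values, roi)
  keep <- g$mag > 0
  out <- setNames(numeric(8), paste0("O8b", 0:7))
  if (!any(keep)) return(out)
  ang <- (atan2(g$gy[keep], g$gx[keep]) * 180 / pi) %% 180
  bin <- pmin(floor(ang / 22.5) + 1L, 8L)
  w <- g$mag[keep]
  out[] <- vapply(1:8, function(k) sum(w[bin == k]), numeric(1))
  out / sum(out)
}
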