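# Gabor transform (GT) features: mean response magnitude of a bank of 24
# complex Gabor kernels (6 wavelengths x 4 orientations).

.gabor_lambdas <- c(4, 6, 8, 12, 16, 24)
.gabor_orientations <- c(H = 0, V = 90, N = 45, Z = 135)

# Complex Gabor kernel: isotropic Gaussian envelope (sigma = lambda / 2,
# truncated at +/- 3 sigma) times a complex carrier along the orientation.
# The carrier's envelope-weighted mean is subtracted so the kernel has zero
# DC response, and the kernel is scaled by the envelope mass so responses
# are on the scale of a local gray-level contrast.
gabor_kernel <- function(lambda, theta_deg) {
  sigma <- lambda / 2
  R <- ceiling(3 * sigma)
  d <- seq(-R, R)
  dr <- matrix(d, 2 * R + 1, 2 * R + 1)
  dc <- t(dr)
  env <- exp(-(dr^2 + dc^2) / (2 * sigma^2))
  th <- theta_deg * pi / 180
  phase <- 2 * pi * (dc * cos(th) + dr * sin(th)) / lambda
  carrier <- exp(1i * phase)
  k <- env * (carrier - sum(env * carrier) / sum(env))
  k / sum(env)
}

# Package-level cache of padded kernel FFTs keyed by (pad dims, lambda,
# orientation); kernels depend only on these.
.gabor_cache <- new.env(parent = emptyenv())

gabor_kernel_fft <- function(lambda, theta_deg, P, Q) {
  key <- paste(P, Q, lambda, theta_deg, sep = "_")
  got <- .gabor_cache[[key]]
  if (!is.null(got)) return(got)
  k <- gabor_kernel(lambda, theta_deg)
  R <- (nrow(k) - 1L) / 2L
  pad <- matrix(0 + 0i, P, Q)
  rows <- ((-(-R:R)) %% P) + 1L   # wrapped position for offset -dr
  cols <- ((-(-R:R)) %% Q) + 1L
  pad[rows, cols] <- k
  out <- fft(pad)
  .gabor_cache[[key]] <- out
  out
}

#' Gabor transform (GT) features
#'
#' Convolves the gray channel with complex Gabor kernels at wavelengths 4,
#' 6, 8, 12, 16 and 24 px (Gaussian envelope sigma = half the wavelength,
#' truncated at three sigma) and orientations H = 0, V = 90, N = 45 and
#' Z = 135 degrees (direction of the carrier modulation, measured from the
#' horizontal image axis). Each feature is the mean response magnitude over
#' the region pixels whose full kernel support lies inside the image;
#' kernels are DC-corrected, so a constant channel gives zero magnitude
#' everywhere. Wavelengths for which no region pixel has full support yield
#' `NA`; if even the smallest kernel has no supported pixel the region is
#' too small and an error is raised.
#'
#' Feature names follow the `Gab<lambda><orientation><sigma>Mag` convention
#' (e.g. `Gab8V4Mag`: wavelength 8, vertical modulation, sigma 4).
#'
#' @inheritParams hist_features
#' @return Named numeric vector of 24 features.
#' @export
gabor_features <- function(values, roi) {
  if (!any(roi)) abort("empty region of interest")
  h <- nrow(values); w <- ncol(values)
  Rmax <- ceiling(3 * max(.gabor_lambdas) / 2)
  P <- stats::nextn(h + 2 * Rmax, c(2, 3, 5))
  Q <- stats::nextn(w + 2 * Rmax, c(2, 3, 5))
  pad <- matrix(0, P, Q)
  pad[1:h, 1:w] <- values
  img_fft <- fft(pad)

  out <- numeric(0)
  for (lambda in .gabor_lambdas) {
    R <- ceiling(3 * (lambda / 2))
    valid <- matrix(FALSE, h, w)
    if (h >= 2 * R + 1 && w >= 2 * R + 1) {
      valid[(R + 1):(h - R), (R + 1):(w - R)] <- TRUE
    }
    sel <- roi & valid
    for (oname in names(.gabor_orientations)) {
      nm <- sprintf("Gab%d%s%dMag", lambda, oname, lambda / 2)
      if (!any(sel)) {
        out[nm] <- NA_real_
        next
      }
      kf <- gabor_kernel_fft(lambda, .gabor_orientations[[oname]], P, Q)
      resp <- fft(img_fft * kf, inverse = TRUE) / (P * Q)
      out[nm] <- mean(Mod(resp[1:h, 1:w][sel]))
    }
  }
  if (all(is.na(out[1:4]))) {
    abort("region smaller than the smallest Gabor kernel support")
  }
  out
}
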