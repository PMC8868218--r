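#' Causal autoregressive model (AM) features
#'
#' Fits the causal raster-scan prediction model: each pixel's brightness is
#' predicted from its left, top-left, top and top-right neighbors,
#' `I(s) ~ theta1 L + theta2 TL + theta3 T + theta4 TR`, by least squares
#' over all region pixels whose four causal neighbors lie inside the
#' region. Rank-deficient designs (e.g. a constant region) take the
#' minimum-norm solution, so a constant region yields
#' `theta = (1/4, 1/4, 1/4, 1/4)`. `Sigma` is the root mean squared
#' prediction residual.
#'
#' @inheritParams hist_features
#' @return Named numeric vector of 5 features (`Teta1` ... `Teta4`,
#'   `Sigma`).
#' @export
ar_features <- function(values, roi) {
  h <- nrow(values); w <- ncol(values)
  ok <- matrix(FALSE, h, w)
  ok[2:h, 2:(w - 1)] <-
    roi[2:h, 2:(w - 1)] &
    roi[2:h, 1:(w - 2)] &          # left
    roi[1:(h - 1), 1:(w - 2)] &    # top-left
    roi[1:(h - 1), 2:(w - 1)] &    # top
    roi[1:(h - 1), 3:w]            # top-right
  if (!any(ok)) abort("no region pixels with all four causal neighbors")
  idx <- which(ok, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  X <- cbind(
    values[cbind(r, c - 1L)],
    values[cbind(r - 1L, c - 1L)],
    values[cbind(r - 1L, c)],
    values[cbind(r - 1L, c + 1L)]
  )
  y <- values[ok]
  theta <- min_norm_lsq(X, y)
  resid <- y - as.numeric(X %*% theta)
  c(setNames(theta, paste0("Teta", 1:4)), Sigma = sqrt(mean(resid^2)))
}
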