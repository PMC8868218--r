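# Internal numeric helpers shared across modules.

# Round half away from zero (all inputs here are non-negative). base::round()
# rounds half to even, which disagrees with the gray-level mapping convention.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Population central moments of a numeric vector; skewness/kurtosis fall back
# to 0 for degenerate (zero-variance) samples.
dist_moments <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v > 0) {
    skew <- mean((x - m)^3) / v^1.5
    kurt <- mean((x - m)^4) / v^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  c(Mean = m, Variance = v, Skewness = skew, Kurtosis = kurt)
}

# Smallest value in `levels` whose empirical CDF (from `counts`) reaches q.
counts_percentile <- function(counts, levels, q) {
  cdf <- cumsum(counts) / sum(counts)
  levels[which(cdf >= q - 1e-12)[1]]
}

# Shift a matrix by (dr, dc), padding with NA; used for pairwise offsets.
shift_matrix <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_real_, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Logical-mask erosion by the 4-neighborhood (pixels whose N/S/E/W neighbors
# are all inside the mask and the image); the interior on which central
# differences are defined.
erode4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  pad[2:(h + 1), 2:(w + 1)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
}

# Minimum-norm least-squares solution via SVD (rank-deficient designs get the
# pseudoinverse solution).
min_norm_lsq <- function(X, y) {
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(s$d)
  pos <- s$d > tol
  dinv <- ifelse(pos, 1 / s$d, 0)
  as.numeric(s$v %*% (dinv * crossprod(s$u, y)))
}

`%||%` <- rlang::`%||%`
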