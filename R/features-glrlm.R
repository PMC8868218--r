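# Gray-level run-length matrix (GRLM) features.

# Maximal same-gray runs along one direction, restricted to the region: a
# run breaks at a gray-level change, at the region boundary, and at the
# image edge. Returns a run matrix p[gray level, run length].
run_matrix <- function(values, roi, direction, n_levels) {
  h <- nrow(values); w <- ncol(values)
  lines <- switch(direction,
    "0" = lapply(seq_len(h), function(r) cbind(r, seq_len(w))),
    "90" = lapply(seq_len(w), function(c) cbind(seq_len(h), c)),
    # 45 degrees: up-right diagonals (constant r + c)
    "45" = lapply(2:(h + w), function(s) {
      r <- seq(min(s - 1, h), max(1, s - w))
      cbind(r, s - r)
    }),
    # 135 degrees: down-right diagonals (constant r - c)
    "135" = lapply((1 - w):(h - 1), function(d) {
      r <- seq(max(1, 1 + d), min(h, w + d))
      cbind(r, r - d)
    }),
    abort(paste("unknown run direction:", direction))
  )
  max_len <- max(h, w)
  p <- matrix(0, n_levels, max_len)
  for (ln in lines) {
    v <- values[ln]
    inr <- roi[ln]
    # break runs at out-of-region pixels by recoding them to level 0
    v[!inr] <- 0L
    r <- rle(as.integer(v))
    keep <- r$values > 0L
    if (!any(keep)) next
    for (i in which(keep)) {
      p[r$values[i], r$lengths[i]] <- p[r$values[i], r$lengths[i]] + 1
    }
  }
  p
}

glrlm_from_matrix <- function(p, n_pixels) {
  nr <- sum(p)
  lens <- seq_len(ncol(p))
  by_len <- colSums(p)
  by_lev <- rowSums(p)
  c(
    RLNonUni = sum(by_len^2) / nr,
    GLevNonUn = sum(by_lev^2) / nr,
    LngREmph = sum(sweep(p, 2, lens^2, "*")) / nr,
    ShrtREmp = sum(sweep(p, 2, 1 / lens^2, "*")) / nr,
    Fraction = nr / n_pixels,
    MRLNonUni = sum(by_len^2) / nr^2,
    MGLevNonUn = sum(by_lev^2) / nr^2
  )
}

#' Gray-level run-length matrix (GRLM) features
#'
#' Counts maximal runs of equal gray level inside the region along the
#' horizontal, vertical, 45-degree and 135-degree directions. With run
#' matrix `p(i, l)`, `N_r` total runs and `N_p` region pixels, the seven
#' features are: run-length non-uniformity `sum_l (sum_i p)^2 / N_r`,
#' gray-level non-uniformity `sum_i (sum_l p)^2 / N_r`, long-run emphasis
#' `sum p l^2 / N_r`, short-run emphasis `sum p / l^2 / N_r`, fraction of
#' image in runs `N_r / N_p`, and the moment (run-count normalized)
#' variants of the two non-uniformities (`.../N_r^2`). Features are
#' averaged over the four directions.
#'
#' @inheritParams hist_features
#' @return Named numeric vector of 7 features.
#' @export
glrlm_features <- function(values, roi, n_levels = 64) {
  if (!any(roi)) abort("empty region of interest")
  np <- sum(roi)
  per_dir <- vapply(
    c("0", "45", "90", "135"),
    function(d) glrlm_from_matrix(run_matrix(values, roi, d, n_levels), np),
    numeric(7)
  )
  rowMeans(per_dir)
}

# Requantize channel gray levels [1, 2^from_bits] onto [1, 2^to_bits] by
# uniform binning; identity when the depths match.
requantize <- function(values, from_bits = 8, to_bits = 6) {
  if (to_bits >= from_bits) return(values)
  step <- 2^(from_bits - to_bits)
  out <- (values - 1L) %/% as.integer(step) + 1L
  attr(out, "bit_depth") <- to_bits
  out
}
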