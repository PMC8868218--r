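# Gray-level co-occurrence matrix features (symmetric GLCM and asymmetric
# GLCH variants) in the classical Haralick form.

#' Co-occurrence configuration
#'
#' Offsets and conventions for the co-occurrence families: pair distances
#' (default 1..9), the four directions (0, 45, 90, 135 degrees), and the
#' entropy logarithm base (natural log by default; use 2 for bits).
#'
#' @param distances Integer vector of pair distances (>= 1).
#' @param directions Subset of `c(0, 45, 90, 135)` degrees.
#' @param log_base Base of the entropy logarithms.
#' @return A list of class `glcm_config`.
#' @export
glcm_config <- function(distances = 1:9, directions = c(0, 45, 90, 135),
                        log_base = exp(1)) {
  stopifnot(all(distances >= 1), all(directions %in% c(0, 45, 90, 135)))
  structure(
    list(
      distances = as.integer(distances), directions = directions,
      log_base = log_base
    ),
    class = "glcm_config"
  )
}

# (dr, dc) offset for a direction (degrees) and distance, in matrix
# row/column coordinates with rows increasing downwards.
glcm_offset <- function(direction, d) {
  switch(as.character(direction),
    "0" = c(0L, d),      # horizontal
    "90" = c(d, 0L),     # vertical
    "45" = c(-d, d),     # up-right
    "135" = c(d, d)      # down-right
  )
}

# Raw co-occurrence count matrix for one offset: ordered pairs (s, s + off)
# with both pixels in the region.
glcm_counts <- function(values, roi, dr, dc, n_levels) {
  sh_v <- shift_matrix(values * 1.0, -dr, -dc)  # value at s + offset
  sh_m <- shift_matrix(roi * 1.0, -dr, -dc) == 1
  sh_m[is.na(sh_m)] <- FALSE
  sel <- roi & sh_m
  if (!any(sel)) return(NULL)
  i <- values[sel]
  j <- as.integer(sh_v[sel])
  counts <- tabulate((i - 1L) * n_levels + j, nbins = n_levels^2)
  matrix(counts, n_levels, n_levels, byrow = TRUE)
}

# Cached level-index matrices per matrix size G.
.glcm_idx_cache <- new.env(parent = emptyenv())
glcm_index_mats <- function(G) {
  key <- as.character(G)
  got <- .glcm_idx_cache[[key]]
  if (!is.null(got)) return(got)
  ii <- matrix(seq_len(G), G, G)
  out <- list(
    ii = ii, jj = t(ii),
    sum_f = as.vector(ii + t(ii)),        # i + j in 2..2G
    dif_f = as.vector(abs(ii - t(ii))),   # |i - j| in 0..G-1
    dif2 = (ii - t(ii))^2
  )
  .glcm_idx_cache[[key]] <- out
  out
}

# Haralick features from one count matrix (already symmetrized for GLCM).
haralick_features <- function(C, log_base) {
  total <- sum(C)
  P <- C / total
  G <- nrow(P)
  lev <- seq_len(G)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sigx <- sqrt(sum((lev - mux)^2 * px))
  sigy <- sqrt(sum((lev - muy)^2 * py))
  im <- glcm_index_mats(G)
  ii <- im$ii; jj <- im$jj
  lg <- function(x) ifelse(x > 0, log(x, base = log_base), 0)
  # diagonal / anti-diagonal marginals via grouped sums
  k_sum <- 2:(2 * G)
  p_sum <- as.vector(rowsum(as.vector(P), im$sum_f))
  k_dif <- 0:(G - 1)
  p_dif <- as.vector(rowsum(as.vector(P), im$dif_f))
  sum_avg <- sum(k_sum * p_sum)
  dif_avg <- sum(k_dif * p_dif)
  # a marginal concentrated on one gray level has zero variance (up to
  # accumulation fuzz): correlation is 0 by convention
  correlat <- if (sigx > 1e-7 && sigy > 1e-7) {
    (sum(ii * jj * P) - mux * muy) / (sigx * sigy)
  } else 0
  c(
    Area = total,
    AngScMom = sum(P^2),
    Contrast = sum(im$dif2 * P),
    Correlat = correlat,
    SumOfSqs = sum((ii - mux)^2 * P),
    InvDefMom = sum(P / (1 + im$dif2)),
    SumAverg = sum_avg,
    SumEntrp = -sum(p_sum * lg(p_sum)),
    SumVarnc = sum((k_sum - sum_avg)^2 * p_sum),
    Entropy = -sum(P * lg(P)),
    DifVarnc = sum((k_dif - dif_avg)^2 * p_dif),
    DifEntrp = -sum(p_dif * lg(p_dif))
  )
}

#' Co-occurrence matrix features (GLCM / GLCH)
#'
#' For every direction x distance offset, counts ordered pairs of region
#' pixels `(s, s + offset)`; the symmetric variant (GLCM) uses `C + t(C)`,
#' the asymmetric variant (GLCH) the raw ordered counts. Twelve Haralick
#' features are computed from each normalized matrix — pair count (`Area`),
#' angular second moment, contrast, correlation, sum of squares
#' (gray-level variance about the row-marginal mean), inverse difference
#' moment, sum average/entropy/variance from the diagonal marginal,
#' entropy, and difference variance/entropy from the anti-diagonal marginal
#' (`0 log 0 = 0`; correlation of a zero-variance matrix is 0) — and
#' averaged over all offsets with at least one valid pair.
#'
#' @inheritParams hist_features
#' @param config A [glcm_config()].
#' @param symmetric `TRUE` for GLCM, `FALSE` for GLCH.
#' @param per_offset If `TRUE`, return the per-offset feature tibble
#'   instead of the offset-averaged vector.
#' @return Named numeric vector of 12 features (or a tibble when
#'   `per_offset`).
#' @export
glcm_features <- function(values, roi, config = glcm_config(),
                          n_levels = 64, symmetric = TRUE,
                          per_offset = FALSE) {
  if (!any(roi)) abort("empty region of interest")
  offsets <- tidyr::expand_grid(
    direction = config$directions, distance = config$distances
  )
  vals <- matrix(
    NA_real_, 12, nrow(offsets),
    dimnames = list(feature_names()$GLCM, NULL)
  )
  for (o in seq_len(nrow(offsets))) {
    off <- glcm_offset(offsets$direction[o], offsets$distance[o])
    C <- glcm_counts(values, roi, off[1], off[2], n_levels)
    if (is.null(C)) next
    if (symmetric) C <- C + t(C)
    vals[, o] <- haralick_features(C, config$log_base)
  }
  ok <- !is.na(vals[1, ])
  if (!any(ok)) abort("no valid pixel pairs at any co-occurrence offset")
  if (per_offset) {
    tab <- tidyr::expand_grid(offsets, feature = rownames(vals))
    tab$value <- as.vector(vals)
    return(tab[!is.na(tab$value), ])
  }
  rowMeans(vals[, ok, drop = FALSE])
}
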