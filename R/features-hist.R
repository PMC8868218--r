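#' Histogram statistics (HS) features
#'
#' First-order statistics of the gray-level histogram over a region,
#' ignoring spatial arrangement. Fourteen features: region area (pixel
#' count), population mean/variance, skewness (`mu3 / sigma^3`), excess
#' kurtosis (`mu4 / sigma^4 - 3`; both 0 for a constant region), the 1st,
#' 10th, 50th, 90th and 99th percentiles (smallest gray level whose CDF
#' reaches the quantile), the dominant gray level at bin widths 1 and 10
#' (modal position; for width 10, the lower gray level of the modal bin),
#' and the corresponding maximal bin counts normalized by region area.
#'
#' @param values Integer gray matrix in `[1, 2^n]` (see
#'   [channel_variants()]).
#' @param roi Logical region mask (non-empty).
#' @param n_levels Number of gray levels (`2^n`).
#' @param wide_bin Width of the coarse dominant/maximum bins.
#' @return Named numeric vector of 14 features (`Area`, `Mean`, `Variance`,
#'   `Skewness`, `Kurtosis`, `Perc01` ... `Perc99`, `Domn01`, `Domn10`,
#'   `Maxm01`, `Maxm10`).
#' @export
hist_features <- function(values, roi, n_levels = 256, wide_bin = 10) {
  if (!any(roi)) abort("empty region of interest")
  x <- values[roi]
  N <- length(x)
  counts <- tabulate(x, nbins = n_levels)
  mom <- dist_moments(x)
  qs <- c(0.01, 0.10, 0.50, 0.90, 0.99)
  perc <- vapply(qs, function(q) {
    counts_percentile(counts, seq_len(n_levels), q)
  }, numeric(1))
  mode1 <- which.max(counts)
  wide_idx <- (x - 1L) %/% wide_bin
  wide_counts <- tabulate(wide_idx + 1L, nbins = (n_levels - 1L) %/% wide_bin + 1L)
  mode10 <- (which.max(wide_counts) - 1L) * wide_bin + 1L
  c(
    Area = N,
    mom,
    setNames(perc, c("Perc01", "Perc10", "Perc50", "Perc90", "Perc99")),
    Domn01 = mode1,
    Domn10 = mode10,
    Maxm01 = max(counts) / N,
    Maxm10 = max(wide_counts) / N
  )
}
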