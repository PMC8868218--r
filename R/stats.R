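# Distribution routing and the before/after and across-repetition
# comparisons of the statistical pipeline.

#' Route a sample by normality
#'
#' Shapiro-Wilk test at the 5% level: a sample is routed `"gaussian"` when
#' `p >= 0.05`, `"non_gaussian"` otherwise. Degenerate (constant) samples
#' cannot be tested and are routed `"non_gaussian"` with a warning.
#'
#' @param x Numeric sample, `n >= 3`.
#' @return `"gaussian"` or `"non_gaussian"`.
#' @export
route_test <- function(x) {
  if (length(x) < 3) abort("need at least 3 observations to route")
  p <- tryCatch(shapiro.test(x)$p.value, error = function(e) {
    warn(paste("degenerate sample, routed non-Gaussian:", conditionMessage(e)))
    0
  })
  if (is.na(p)) p <- 0
  if (p >= 0.05) "gaussian" else "non_gaussian"
}

#' Compare before/after-exercise paired samples
#'
#' Two-sided paired comparison of BS 0 vs BS 1 measurements: a paired
#' t-test on the Gaussian route, the Wilcoxon matched-pairs signed-rank
#' test otherwise (zero differences dropped, mid-rank ties, normal
#' approximation). Identical samples on the t route return `p = 1`;
#' all-zero differences on the Wilcoxon route are an error (no ranks
#' remain).
#'
#' @param before,after Paired numeric vectors of equal length.
#' @param route `"gaussian"` or `"non_gaussian"`; defaults to routing the
#'   differences with [route_test()].
#' @return Two-sided p-value.
#' @export
compare_bs <- function(before, after, route = NULL) {
  if (length(before) != length(after)) {
    abort("paired samples must have equal length")
  }
  d <- after - before
  route <- route %||% route_test(d)
  if (route == "gaussian") {
    if (all(d == 0) || sd(d) == 0 && mean(d) == 0) return(1)
    if (sd(d) == 0) return(0)  # identical non-zero shift: t is infinite
    t.test(after, before, paired = TRUE)$p.value
  } else {
    if (all(d == 0)) abort("all paired differences are zero on Wilcoxon route")
    suppressWarnings(
      wilcox.test(after, before, paired = TRUE, exact = FALSE)$p.value
    )
  }
}

# Greenhouse-Geisser sphericity estimate from the condition covariance
# matrix, clamped to its theoretical range [1/(k-1), 1].
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  dbar <- mean(diag(S)); sbar <- mean(S)
  row_means <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
  eps <- if (den <= 0 || !is.finite(den)) 1 else num / den
  clamp(eps, 1 / (k - 1), 1)
}

#' Compare measurements across exercise repetitions
#'
#' Omnibus and pairwise comparisons of a complete horses x repetitions
#' matrix. Gaussian route: repeated-measures one-way ANOVA with
#' Greenhouse-Geisser corrected degrees of freedom, followed by Tukey's
#' multiple-comparison test on the repetition means. Non-Gaussian route:
#' Friedman test followed by Dunn's multiple-comparison test
#' (Bonferroni-adjusted within the comparison family).
#'
#' @param mat Numeric matrix, rows = horses (subjects), columns =
#'   repetitions; no missing cells.
#' @param route `"gaussian"` or `"non_gaussian"`; defaults to routing the
#'   pooled residuals.
#' @return A list with `method`, omnibus `p_value`, `epsilon` (Gaussian
#'   route), `statistic`, and a tibble `pairwise` (`re_a`, `re_b`,
#'   `p_value`).
#' @export
compare_re <- function(mat, route = NULL) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) abort("missing cells in the horses x repetitions matrix")
  n <- nrow(mat); k <- ncol(mat)
  route <- route %||% route_test(as.vector(scale(mat, scale = FALSE)))
  col_means <- colMeans(mat)
  if (route == "gaussian") {
    grand <- mean(mat)
    ss_treat <- n * sum((col_means - grand)^2)
    ss_subj <- k * sum((rowMeans(mat) - grand)^2)
    ss_err <- sum((mat - outer(rowMeans(mat), col_means, "+") + grand)^2)
    ms_treat <- ss_treat / (k - 1)
    ms_err <- ss_err / ((n - 1) * (k - 1))
    if (ss_treat <= .Machine$double.eps * max(1, abs(grand))) {
      f_stat <- 0; p <- 1; eps <- 1
    } else {
      eps <- gg_epsilon(mat)
      f_stat <- ms_treat / ms_err
      p <- pf(f_stat, eps * (k - 1), eps * (n - 1) * (k - 1),
              lower.tail = FALSE)
    }
    pairs <- tidyr::expand_grid(re_a = 1:k, re_b = 1:k)
    pairs <- dplyr::filter(pairs, .data$re_a < .data$re_b)
    pairs$p_value <- purrr::map2_dbl(pairs$re_a, pairs$re_b, function(a, b) {
      if (ms_err == 0) return(as.numeric(col_means[a] == col_means[b]))
      q <- abs(col_means[a] - col_means[b]) / sqrt(ms_err / n)
      ptukey(q, k, (n - 1) * (k - 1), lower.tail = FALSE)
    })
    list(
      method = "rm_anova_gg", p_value = p, epsilon = eps,
      statistic = f_stat, pairwise = pairs
    )
  } else {
    ranks <- t(apply(mat, 1, rank))
    rbar <- colMeans(ranks)
    chi <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
    p <- stats::pchisq(chi, k - 1, lower.tail = FALSE)
    if (chi == 0) p <- 1
    m <- k * (k - 1) / 2
    pairs <- tidyr::expand_grid(re_a = 1:k, re_b = 1:k)
    pairs <- dplyr::filter(pairs, .data$re_a < .data$re_b)
    pairs$p_value <- purrr::map2_dbl(pairs$re_a, pairs$re_b, function(a, b) {
      z <- abs(rbar[a] - rbar[b]) / sqrt(k * (k + 1) / (6 * n))
      clamp(2 * pnorm(z, lower.tail = FALSE) * m, 0, 1)
    })
    list(
      method = "friedman_dunn", p_value = p, epsilon = NA_real_,
      statistic = chi, pairwise = pairs
    )
  }
}
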