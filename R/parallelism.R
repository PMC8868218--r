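# ANCOVA slope-parallelism: the selection criterion relating a texture
# feature's across-repetition trend to a blood biomarker's.

#' Rescale a feature series onto a biomarker's numeric scale
#'
#' A texture feature (arbitrary gray-level units) and a biomarker (e.g.
#' U/L) are not commensurate; before slope comparison the feature series is
#' mapped affinely so its sample mean and variance match the biomarker's.
#' Degenerate (zero-variance) feature series cannot be aligned and return
#' `NULL`.
#'
#' @param feature_y Numeric feature series.
#' @param biomarker_y Numeric biomarker series (the reference scale).
#' @return The rescaled feature series, or `NULL` when degenerate.
#' @export
align_series <- function(feature_y, biomarker_y) {
  s <- sd(feature_y)
  if (!is.finite(s) || s == 0 || sd(biomarker_y) == 0) return(NULL)
  (feature_y - mean(feature_y)) / s * sd(biomarker_y) + mean(biomarker_y)
}

#' Test slope parallelism between a biomarker and a feature series
#'
#' Implements the slope-parallelism procedure on a pair of data series
#' sharing the repetition index as regressor: fit separate simple
#' regressions per group, test slope equality by the extra-sum-of-squares
#' F-test (interaction vs common-slope model); if slopes are
#' indistinguishable (`p > alpha`), refit with a pooled slope and test
#' intercept equality the same way, pooling the intercept too when that
#' test also exceeds `alpha`. The pair is flagged `related` when the
#' slopes are parallel and both series show evidence of linearity — each
#' group's own slope significantly non-zero (`p_slope_nonzero` is the
#' weaker of the two per-group tests; the pooled slope's own test is
#' reported as `p_pooled_nonzero` when pooling occurred).
#'
#' @param pair A data frame with columns `x` (repetition index), `y`
#'   (value) and `group` (two levels: biomarker label and feature label),
#'   at least 3 points per group.
#' @param alpha Significance level for the equality tests.
#' @param alpha_nz Significance level for the non-zero slope test.
#' @param scale `"align"` (default) rescales the feature group onto the
#'   biomarker group's scale with [align_series()]; `"raw"` compares the
#'   series as given.
#' @param feature_group Which `group` level is the feature (rescaled
#'   under `"align"`); defaults to the second level.
#' @return An object of class `parallelism_fit`; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' pair <- data.frame(
#'   x = rep(1:6, 4),
#'   y = c(2 * rep(1:6, 2) + rnorm(12, 0, .1),
#'         2 * rep(1:6, 2) + 5 + rnorm(12, 0, .1)),
#'   group = rep(c("CPK", "feature"), each = 12)
#' )
#' fit <- fit_parallelism(pair, scale = "raw")
#' glance(fit)
#' @export
fit_parallelism <- function(pair, alpha = 0.05, alpha_nz = 0.05,
                            scale = c("align", "raw"),
                            feature_group = NULL) {
  scale <- match.arg(scale)
  stopifnot(all(c("x", "y", "group") %in% names(pair)))
  pair <- tibble::as_tibble(pair)
  groups <- unique(as.character(pair$group))
  if (length(groups) != 2) abort("pair must contain exactly two groups")
  counts <- table(pair$group)
  if (any(counts < 3)) abort("need at least 3 points per group")
  if (length(unique(pair$x)) < 2) abort("degenerate regressor: all x equal")
  feature_group <- feature_group %||% groups[2]

  if (scale == "align") {
    fy <- pair$y[pair$group == feature_group]
    by <- pair$y[pair$group != feature_group]
    aligned <- align_series(fy, by)
    if (is.null(aligned)) {
      abort("degenerate feature series: zero variance, cannot align")
    }
    pair$y[pair$group == feature_group] <- aligned
  }

  # Closed-form ANCOVA via per-group regression sums; identical to the
  # extra-sum-of-squares F-tests between the interaction, common-slope and
  # single-line linear models (checked against lm()/anova() in the tests).
  is_a <- pair$group == groups[1]
  xa <- pair$x[is_a]; ya <- pair$y[is_a]
  xb <- pair$x[!is_a]; yb <- pair$y[!is_a]
  gsum <- function(x, y) {
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    b <- if (sxx > 0) sxy / sxx else NA_real_
    list(n = n, sxx = sxx, sxy = sxy, syy = syy, b = b,
         xbar = mean(x), ybar = mean(y), sse = syy - sxy^2 / max(sxx, 1e-300))
  }
  A <- gsum(xa, ya); B <- gsum(xb, yb)
  if (!is.finite(A$b) || !is.finite(B$b)) {
    abort("degenerate regressor within a group: all x equal")
  }
  n <- A$n + B$n
  slopes <- setNames(c(A$b, B$b), groups)

  ss_full <- A$sse + B$sse
  b_common <- (A$sxy + B$sxy) / (A$sxx + B$sxx)
  ss_common <- (A$syy - 2 * b_common * A$sxy + b_common^2 * A$sxx) +
    (B$syy - 2 * b_common * B$sxy + B$sxx * b_common^2)
  S1 <- gsum(pair$x, pair$y)
  ss_single <- S1$sse

  sst <- S1$syy
  ss_tol <- 1e-12 * max(sst, 1)
  if (ss_common - ss_full <= ss_tol) {
    f_slope <- 0; p_slope_equal <- 1
  } else {
    f_slope <- (ss_common - ss_full) / (ss_full / (n - 4))
    p_slope_equal <- pf(f_slope, 1, n - 4, lower.tail = FALSE)
    if (!is.finite(f_slope)) { f_slope <- Inf; p_slope_equal <- 0 }
  }

  parallel <- p_slope_equal > alpha
  pooled_slope <- if (parallel) b_common else NA_real_
  p_intercept_equal <- NA_real_
  pooled_intercept <- NA_real_
  if (parallel) {
    if (ss_single - ss_common <= ss_tol) {
      p_intercept_equal <- 1
    } else {
      f_int <- (ss_single - ss_common) / (ss_common / (n - 3))
      p_intercept_equal <- pf(f_int, 1, n - 3, lower.tail = FALSE)
      if (!is.finite(p_intercept_equal)) p_intercept_equal <- 1
    }
    if (p_intercept_equal > alpha) {
      pooled_intercept <- S1$ybar - S1$b * S1$xbar
    }
  }
  slope_p <- function(b, sse, sxx, df) {
    if (sse <= ss_tol) return(if (abs(b) > 0) 0 else 1)
    se <- sqrt((sse / df) / sxx)
    2 * pt(abs(b) / se, df, lower.tail = FALSE)
  }
  # evidence of linearity: each series' own slope must be non-zero (the
  # weaker of the two per-group tests); the pooled slope's test is also
  # reported when pooling occurred
  p_slope_nonzero <- max(
    slope_p(A$b, A$sse, A$sxx, A$n - 2),
    slope_p(B$b, B$sse, B$sxx, B$n - 2)
  )
  p_pooled_nonzero <- if (parallel) {
    slope_p(b_common, ss_common, A$sxx + B$sxx, n - 3)
  } else NA_real_
  related <- parallel && p_slope_nonzero < alpha_nz

  structure(
    list(
      groups = groups, slopes = slopes,
      f_slope = f_slope, p_slope_equal = p_slope_equal,
      pooled_slope = pooled_slope,
      p_intercept_equal = p_intercept_equal,
      pooled_intercept = pooled_intercept,
      p_slope_nonzero = p_slope_nonzero,
      p_pooled_nonzero = p_pooled_nonzero,
      related = related, alpha = alpha, alpha_nz = alpha_nz,
      scale = scale, data = pair
    ),
    class = "parallelism_fit"
  )
}

#' @export
print.parallelism_fit <- function(x, ...) {
  cat(sprintf(
    "<parallelism_fit> %s vs %s\n", x$groups[1], x$groups[2]
  ))
  cat(sprintf(
    "  slopes: %.4g / %.4g; slope equality p = %.4g\n",
    x$slopes[1], x$slopes[2], x$p_slope_equal
  ))
  if (!is.na(x$pooled_slope)) {
    cat(sprintf(
      "  pooled slope: %.4g (non-zero p = %.3g); intercept equality p = %.4g\n",
      x$pooled_slope, x$p_slope_nonzero, x$p_intercept_equal
    ))
  }
  cat(sprintf("  related: %s\n", x$related))
  invisible(x)
}

#' @rdname fit_parallelism
#' @param x A `parallelism_fit`.
#' @param ... Unused.
#' @export
tidy.parallelism_fit <- function(x, ...) {
  tibble::tibble(
    group = c(x$groups, "pooled"),
    slope = c(unname(x$slopes), x$pooled_slope),
    intercept = c(NA_real_, NA_real_, x$pooled_intercept)
  )
}

#' @rdname fit_parallelism
#' @export
glance.parallelism_fit <- function(x, ...) {
  tibble::tibble(
    p_slope_equal = x$p_slope_equal,
    pooled_slope = x$pooled_slope,
    p_intercept_equal = x$p_intercept_equal,
    pooled_intercept = x$pooled_intercept,
    p_slope_nonzero = x$p_slope_nonzero,
    related = x$related
  )
}

#' @rdname fit_parallelism
#' @param object A `parallelism_fit`.
#' @export
autoplot.parallelism_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$x, y = .data$y, color = .data$group)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = "exercise repetition",
      y = "value (biomarker scale)",
      subtitle = sprintf(
        "slope equality p = %.3g%s", object$p_slope_equal,
        if (!is.na(object$pooled_slope)) {
          sprintf("; pooled slope = %.3g", object$pooled_slope)
        } else ""
      )
    ) +
    ggplot2::theme_minimal()
}
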