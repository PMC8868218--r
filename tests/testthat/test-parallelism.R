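make_pair <- function(y1, y2, x = rep(1:6, each = 12),
                      groups = c("A", "B")) {
  n <- length(x)
  tibble::tibble(
    x = rep(x, 2), y = c(y1, y2), group = rep(groups, each = n)
  )
}

test_that("closed-form ANCOVA matches the lm/anova reference route", {
  set.seed(81)
  x <- rep(1:6, each = 12)
  for (i in 1:6) {
    b2 <- sample(c(1.6, 2, 2.8), 1)
    pair <- make_pair(2 * x + rnorm(72, 0, 2), b2 * x + 3 + rnorm(72, 0, 2))
    fit <- fit_parallelism(pair, scale = "raw")
    full <- lm(y ~ group * x, pair)
    common <- lm(y ~ group + x, pair)
    single <- lm(y ~ x, pair)
    expect_equal(fit$p_slope_equal, anova(common, full)[["Pr(>F)"]][2],
                 tolerance = 1e-10)
    expect_equal(unname(fit$slopes),
                 c(coef(lm(y ~ x, pair[pair$group == "A", ]))[2],
                   coef(lm(y ~ x, pair[pair$group == "B", ]))[2]),
                 ignore_attr = TRUE, tolerance = 1e-10)
    if (!is.na(fit$pooled_slope)) {
      expect_equal(fit$pooled_slope, unname(coef(common)["x"]),
                   tolerance = 1e-10)
      expect_equal(fit$p_intercept_equal,
                   anova(single, common)[["Pr(>F)"]][2], tolerance = 1e-10)
      expect_equal(fit$p_pooled_nonzero,
                   summary(common)$coefficients["x", "Pr(>|t|)"],
                   tolerance = 1e-10)
    }
  }
})

test_that("identical series give F = 0, p = 1 and the group's own slope pooled", {
  x <- rep(1:6, each = 2)
  y <- 2 * x + c(0.1, -0.1)
  fit <- fit_parallelism(make_pair(y, y, x = x), scale = "raw")
  expect_equal(fit$p_slope_equal, 1)
  expect_equal(fit$f_slope, 0)
  expect_equal(fit$pooled_slope,
               unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
  expect_equal(fit$p_intercept_equal, 1)
})

test_that("parallel series pool the slope; opposite trends do not", {
  set.seed(82)
  x <- rep(1:6, each = 12)
  pair <- make_pair(2 * x + rnorm(72, 0, 0.4), 2 * x + 5 + rnorm(72, 0, 0.4))
  fit <- fit_parallelism(pair, scale = "raw")
  expect_gt(fit$p_slope_equal, 0.05)
  expect_lt(abs(fit$pooled_slope - 2), 0.15)
  expect_lt(fit$p_intercept_equal, 0.05)    # intercepts differ by 5
  expect_true(is.na(fit$pooled_intercept))
  expect_true(fit$related)

  anti <- make_pair(2 * x + rnorm(72, 0, 0.4), -2 * x + rnorm(72, 0, 0.4))
  fit2 <- fit_parallelism(anti, scale = "raw")
  expect_lt(fit2$p_slope_equal, 0.05)
  expect_true(is.na(fit2$pooled_slope))
  expect_false(fit2$related)
})

test_that("slope-equality p-value is symmetric in group order", {
  set.seed(83)
  x <- rep(1:6, each = 12)
  pair <- make_pair(2 * x + rnorm(72), 1.5 * x + rnorm(72))
  swapped <- pair
  swapped$group <- ifelse(pair$group == "A", "B", "A")
  f1 <- fit_parallelism(pair, scale = "raw")
  f2 <- fit_parallelism(swapped, scale = "raw")
  expect_equal(f1$p_slope_equal, f2$p_slope_equal, tolerance = 1e-12)
})

test_that("pooled slope equals the Sxx-weighted average of group slopes", {
  set.seed(84)
  for (i in 1:5) {
    xa <- sample(1:6, 30, TRUE); xb <- sample(1:8, 40, TRUE)
    ya <- 2 * xa + rnorm(30); yb <- 1.2 * xb + rnorm(40)
    pair <- tibble::tibble(
      x = c(xa, xb), y = c(ya, yb),
      group = rep(c("A", "B"), c(30, 40))
    )
    fit <- fit_parallelism(pair, scale = "raw", alpha = 1e-9)
    if (is.na(fit$pooled_slope)) next
    sxx <- function(x) sum((x - mean(x))^2)
    w <- c(sxx(xa), sxx(xb))
    expect_equal(fit$pooled_slope,
                 sum(w * fit$slopes) / sum(w), tolerance = 1e-9)
  }
})

test_that("scale alignment maps the feature onto the biomarker scale", {
  set.seed(85)
  x <- rep(1:6, each = 12)
  bio <- 180 + 18 * x + rnorm(72, 0, 40)
  feat <- 0.002 * (10 + x + rnorm(72, 0, 40 / 18))  # same shape, tiny units
  aligned <- align_series(feat, bio)
  expect_equal(mean(aligned), mean(bio))
  expect_equal(sd(aligned), sd(bio))
  expect_null(align_series(rep(1, 72), bio))
  fit <- fit_parallelism(make_pair(bio, feat), scale = "align",
                         feature_group = "B")
  expect_gt(fit$p_slope_equal, 0.05)
  # raw mode compares incommensurate slopes and must reject here
  fit_raw <- fit_parallelism(make_pair(bio, feat), scale = "raw")
  expect_lt(fit_raw$p_slope_equal, 0.05)
})

test_that("degenerate inputs are rejected with informative errors", {
  x <- rep(1, 24)
  pair <- make_pair(rnorm(24), rnorm(24), x = rep(1, 24))
  expect_error(fit_parallelism(pair), "degenerate regressor")
  short <- tibble::tibble(x = c(1, 2, 1, 2), y = rnorm(4),
                          group = c("A", "A", "B", "B"))
  expect_error(fit_parallelism(short), "3 points")
  const_feat <- make_pair(2 * rep(1:6, each = 2) + rnorm(12), rep(3, 12),
                          x = rep(1:6, each = 2))
  expect_error(fit_parallelism(const_feat, scale = "align",
                               feature_group = "B"),
               "zero variance")
})

test_that("tidy, glance and autoplot expose the fit", {
  set.seed(86)
  x <- rep(1:6, each = 12)
  fit <- fit_parallelism(
    make_pair(2 * x + rnorm(72), 2 * x + 4 + rnorm(72)), scale = "raw"
  )
  td <- tidy(fit)
  expect_named(td, c("group", "slope", "intercept"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_true(all(c("p_slope_equal", "pooled_slope", "related") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("selection evaluates 528 pairs per model and biomarker and flags the coupled pair", {
  s <- generate_study(small_design(), effect_model(), seed = 91)
  cfg <- pipeline_config(texture = list(families = "HS"))
  ft <- extract_features(s, cfg, conventional = FALSE)
  # restrict to the RGB model for the count check at full channel coverage
  sel <- select_related(
    dplyr::filter(ft, model == "RGB"), s$biomarkers, targets = "CPK"
  )
  per_roi <- dplyr::count(sel, roi)
  # 14 HS features x 3 components x 2 normalization states = 84 per ROI;
  # scaled up by the other 7 families this is the 528-per-model contract
  expect_equal(per_roi$n, rep(14 * 3 * 2, 4))
  n_per_model <- length(unlist(feature_names())) * 3 * 2
  expect_equal(n_per_model, 528)
  # the engineered coupled pair is flagged in the muscle region
  v <- dplyr::filter(sel, feature == "HS.Variance", channel == "R", roi == 3)
  expect_true(v$related)
  expect_s3_class(plot_selection_matrix(sel), "ggplot")
  m <- selection_matrix(sel)
  expect_true(all(c("roi", "family", "model", "channel", "biomarkers") %in%
                    names(m)))
})
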