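# Per-family unit tests: closed-form examples, invariants, and agreement
# with the brute-force oracles on random small images.

test_that("histogram statistics match hand-computed values", {
  # weighted-moment example: values {1,2,2,3,3,3,4,4,5}
  v <- matrix(c(1, 2, 2, 3, 3, 3, 4, 4, 5), 3, 3)
  storage.mode(v) <- "integer"
  f <- hist_features(v, matrix(TRUE, 3, 3), n_levels = 8)
  expect_equal(unname(f["Mean"]), 3)
  expect_equal(unname(f["Variance"]), 12 / 9)
  expect_equal(unname(f["Area"]), 9)
  expect_equal(unname(f["Domn01"]), 3)
  expect_equal(unname(f["Maxm01"]), 3 / 9)
  # percentile monotonicity
  qs <- f[c("Perc01", "Perc10", "Perc50", "Perc90", "Perc99")]
  expect_true(all(diff(qs) >= 0))
  # constant region: zero variance, skewness/kurtosis by convention 0
  cst <- hist_features(matrix(5L, 4, 4), matrix(TRUE, 4, 4), 8)
  expect_equal(unname(cst[c("Variance", "Skewness", "Kurtosis")]), c(0, 0, 0))
  expect_true(all(cst[c("Perc01", "Perc50", "Perc99")] == 5))
  expect_error(hist_features(v, matrix(FALSE, 3, 3)), "empty region")
})

test_that("gradient features have the closed-form ramp behavior", {
  ramp <- matrix(rep(1:10, each = 10), 10, 10)  # unit horizontal ramp
  f <- gradient_features(ramp, matrix(TRUE, 10, 10))
  expect_equal(unname(f["Mean"]), 1)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["NonZeros"]), 1)
  expect_equal(unname(f["Area"]), 64)   # 8x8 interior
  cst <- gradient_features(matrix(3, 6, 6), matrix(TRUE, 6, 6))
  expect_equal(unname(cst[c("Mean", "NonZeros")]), c(0, 0))
  # magnitudes invariant to adding a constant
  set.seed(41)
  v <- random_channel(10, 10, 8)
  f1 <- gradient_features(v, matrix(TRUE, 10, 10))
  f2 <- gradient_features(v + 40L, matrix(TRUE, 10, 10))
  expect_equal(f1, f2)
  expect_error(gradient_features(ramp, matrix(FALSE, 10, 10)), "too thin")
})

test_that("autoregressive fit recovers causal structure", {
  # constant channel: rank-1 design, minimum-norm convention
  f <- ar_features(matrix(9, 8, 8), matrix(TRUE, 8, 8))
  expect_equal(unname(f[1:4]), rep(0.25, 4), tolerance = 1e-10)
  expect_equal(unname(f["Sigma"]), 0, tolerance = 1e-10)
  # row-constant channel with distinct rows: exact reconstruction from the
  # left neighbor (minimum-norm among exact solutions)
  rows <- matrix(rep(c(3, 7, 2, 9, 5, 4, 8, 6), 8), 8, 8, byrow = FALSE)
  f2 <- ar_features(rows, matrix(TRUE, 8, 8))
  oracle <- oracle_ar(rows, matrix(TRUE, 8, 8))
  expect_equal(unname(f2), unname(oracle), tolerance = 1e-8)
  expect_equal(unname(f2["Teta1"]), 1, tolerance = 1e-8)
  expect_equal(unname(f2["Sigma"]), 0, tolerance = 1e-8)
  # white noise: imperfect prediction, small coefficients
  set.seed(42)
  wn <- matrix(sample.int(64, 400, TRUE), 20, 20)
  f3 <- ar_features(wn, matrix(TRUE, 20, 20))
  expect_gt(unname(f3["Sigma"]), 0)
  expect_true(all(abs(f3[1:4]) < 0.6))
})

test_that("Gabor bank is zero on constants and orientation selective", {
  roi <- matrix(TRUE, 80, 80)
  expect_lt(max(gabor_features(matrix(50L, 80, 80), roi)), 1e-10)
  grating <- matrix(0L, 80, 80)
  for (c in 1:80) grating[, c] <- as.integer(round(100 + 50 * sin(2 * pi * c / 8)))
  g <- gabor_features(grating, roi)
  expect_gt(g[["Gab8H4Mag"]], g[["Gab8V4Mag"]])
  expect_gt(g[["Gab8H4Mag"]], g[["Gab8N4Mag"]])
  expect_gt(g[["Gab8H4Mag"]], g[["Gab8Z4Mag"]])
  # shift invariance from the zero-DC kernels
  expect_equal(g, gabor_features(grating + 25L, roi), tolerance = 1e-10)
  # a region too small for the smallest kernel errors
  expect_error(gabor_features(random_channel(10, 10), matrix(TRUE, 10, 10)),
               "smallest Gabor kernel")
})

test_that("Gabor magnitudes match the direct convolution oracle", {
  set.seed(43)
  v <- random_channel(60, 60, 16)
  roi <- matrix(FALSE, 60, 60)
  roi[25:36, 25:36] <- TRUE
  g <- gabor_features(v, roi)
  angles <- c(H = 0, V = 90, N = 45, Z = 135)
  for (lambda in c(4, 8)) {
    for (on in names(angles)) {
      nm <- sprintf("Gab%d%s%dMag", lambda, on, lambda / 2)
      expect_equal(g[[nm]], oracle_gabor(v, roi, lambda, angles[[on]]),
                   tolerance = 1e-9, label = nm)
    }
  }
})

test_that("HOG puts a step edge in the horizontal-gradient bin and sums to 1", {
  step <- matrix(0L, 10, 10); step[, 6:10] <- 10L   # vertical edge
  f <- hog_features(step, matrix(TRUE, 10, 10))
  expect_equal(unname(f["O8b0"]), 1)
  expect_equal(sum(f), 1)
  cst <- hog_features(matrix(4L, 8, 8), matrix(TRUE, 8, 8))
  expect_equal(unname(cst), rep(0, 8))
  set.seed(44)
  v <- random_channel(14, 14, 8)
  expect_equal(sum(hog_features(v, matrix(TRUE, 14, 14))), 1)
})

test_that("run-length features match enumeration closed forms", {
  # constant N x N region, horizontal: one run of length N per row
  N <- 6
  v <- matrix(2L, N, N)
  p <- equitherm:::run_matrix(v, matrix(TRUE, N, N), "0", 4)
  f <- equitherm:::glrlm_from_matrix(p, N^2)
  expect_equal(unname(f["LngREmph"]), N^2)
  expect_equal(unname(f["ShrtREmp"]), 1 / N^2)
  expect_equal(unname(f["Fraction"]), 1 / N)
  # two-level checkerboard: all horizontal runs have length 1
  cb <- (outer(1:8, 1:8, "+") %% 2L) + 1L
  pc <- equitherm:::run_matrix(cb, matrix(TRUE, 8, 8), "0", 2)
  fc <- equitherm:::glrlm_from_matrix(pc, 64)
  expect_equal(unname(fc["Fraction"]), 1)
  expect_equal(unname(fc["LngREmph"]), 1)
  # short <= 1 <= long run emphasis for any input
  set.seed(45)
  v2 <- random_channel(12, 12, 4)
  f2 <- glrlm_features(v2, random_mask(12, 12), n_levels = 4)
  expect_lte(unname(f2["ShrtREmp"]), 1)
  expect_gte(unname(f2["LngREmph"]), 1)
})

test_that("co-occurrence features reproduce the worked examples", {
  # constant region: single-cell matrix
  f <- glcm_features(matrix(3L, 6, 6), matrix(TRUE, 6, 6),
                     glcm_config(distances = 1:2), n_levels = 4)
  expect_equal(unname(f["AngScMom"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["InvDefMom"]), 1)
  expect_equal(unname(f["SumOfSqs"]), 0)
  # 4x4 worked example, horizontal d = 1, symmetric: 24 ordered pairs,
  # P(0,0) = 4/24 = 1/6
  m <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1, 0, 2, 2, 2, 2, 2, 3, 3), 4, 4,
              byrow = TRUE) + 1L
  C <- equitherm:::glcm_counts(m, matrix(TRUE, 4, 4), 0, 1, 4)
  Cs <- C + t(C)
  expect_equal(sum(Cs), 24)
  expect_equal(Cs[1, 1] / sum(Cs), 1 / 6)
  # 0/1 checkerboard, horizontal d = 1, symmetric, base-2 entropy
  cb <- (outer(1:8, 1:8, "+") %% 2L) + 1L
  g <- glcm_features(cb, matrix(TRUE, 8, 8),
                     glcm_config(distances = 1, directions = 0, log_base = 2),
                     n_levels = 2)
  expect_equal(unname(g["Contrast"]), 1)
  expect_equal(unname(g["AngScMom"]), 0.5)
  expect_equal(unname(g["Entropy"]), 1)
})

test_that("symmetric matrices equal their transpose, asymmetric ones need not", {
  set.seed(46)
  v <- random_channel(12, 12, 4)
  roi <- matrix(TRUE, 12, 12)
  C <- equitherm:::glcm_counts(v, roi, 0, 1, 4)
  expect_false(isTRUE(all.equal(C, t(C))))  # generic image: asymmetric
  expect_identical(C + t(C), t(C + t(C)))
})

test_that("90-degree rotation preserves direction-averaged matrix features and permutes Gabor orientations", {
  set.seed(47)
  v <- random_channel(40, 40, 4)
  roi <- random_mask(40, 40)
  rot <- function(m) t(m)[, nrow(m):1]       # 90 degrees counter-clockwise
  vr <- rot(v); roir <- rot(roi)
  f1 <- glcm_features(v, roi, n_levels = 4)
  f2 <- glcm_features(vr, roir, n_levels = 4)
  expect_equal(f1, f2, tolerance = 1e-12)
  g1 <- glrlm_features(v, roi, n_levels = 4)
  g2 <- glrlm_features(vr, roir, n_levels = 4)
  expect_equal(g1, g2, tolerance = 1e-12)
  v8 <- random_channel(96, 96, 200)
  roi8 <- matrix(FALSE, 96, 96); roi8[41:56, 41:56] <- TRUE
  gb1 <- gabor_features(v8, roi8)
  gb2 <- gabor_features(rot(v8), rot(roi8))
  for (l in c(4, 6, 8)) {
    expect_equal(gb1[[sprintf("Gab%dH%dMag", l, l / 2)]],
                 gb2[[sprintf("Gab%dV%dMag", l, l / 2)]], tolerance = 1e-9)
    expect_equal(gb1[[sprintf("Gab%dN%dMag", l, l / 2)]],
                 gb2[[sprintf("Gab%dZ%dMag", l, l / 2)]], tolerance = 1e-9)
  }
})

test_that("all families agree with brute-force oracles on random images", {
  set.seed(48)
  for (i in 1:8) {
    v <- random_channel(12, 12, 4)
    roi <- if (i <= 4) matrix(TRUE, 12, 12) else random_mask(12, 12)
    expect_equal(hist_features(v, roi, n_levels = 4),
                 oracle_hist(v, roi, 4), tolerance = 1e-9)
    expect_equal(gradient_features(v, roi), oracle_gradient(v, roi),
                 tolerance = 1e-9)
    expect_equal(ar_features(v, roi), oracle_ar(v, roi), tolerance = 1e-7)
    expect_equal(hog_features(v, roi), oracle_hog(v, roi), tolerance = 1e-9)
    expect_equal(glrlm_features(v, roi, n_levels = 4),
                 oracle_glrlm(v, roi, 4), tolerance = 1e-9)
    expect_equal(glcm_features(v, roi, n_levels = 4, symmetric = TRUE),
                 oracle_glcm(v, roi, 4, TRUE), tolerance = 1e-9)
    expect_equal(glcm_features(v, roi, n_levels = 4, symmetric = FALSE),
                 oracle_glcm(v, roi, 4, FALSE), tolerance = 1e-9)
  }
})

test_that("extraction is deterministic and enumerates the full combination grid", {
  s <- generate_study(tiny_design(1, 2), effect_model(), seed = 51)
  cfg <- fast_config()
  a <- extract_image_features(s$images$image[[2]], s$masks, cfg)
  b <- extract_image_features(s$images$image[[2]], s$masks, cfg)
  expect_identical(a, b)
  n_feats <- length(unlist(feature_names()[fast_families]))
  counts <- dplyr::count(a, roi)
  expect_equal(counts$n, rep(n_feats * 24, 4))
  per_variant <- dplyr::count(a, roi, model, channel, normalization)
  expect_true(all(per_variant$n == n_feats))
})
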