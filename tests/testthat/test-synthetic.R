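test_that("study bundle has the designed factorial structure", {
  s <- generate_study(tiny_design(n_horses = 1, n_re = 2), effect_model(),
                      seed = 1)
  expect_equal(nrow(s$images), 4)        # 1 horse x 2 RE x 2 BS
  expect_equal(nrow(s$biomarkers), 4)
  expect_setequal(unique(as.vector(s$masks)), 0:4)
  expect_named(
    s$biomarkers,
    c("horse", "re", "bs", biomarker_reference()$biomarker)
  )
  d <- study_design()
  s_rows <- d$n_horses * d$n_re * d$n_bs
  expect_equal(s_rows, 144)              # the default repeated-exercise layout
})

test_that("same seed reproduces a bit-identical bundle", {
  a <- generate_study(tiny_design(2, 3), effect_model(), seed = 42)
  b <- generate_study(tiny_design(2, 3), effect_model(), seed = 42)
  expect_identical(a$images$field, b$images$field)
  expect_identical(a$images$image, b$images$image)
  expect_identical(a$biomarkers, b$biomarkers)
  c <- generate_study(tiny_design(2, 3), effect_model(), seed = 43)
  expect_false(identical(a$biomarkers, c$biomarkers))
})

test_that("null effect freezes images and biomarker series", {
  eff <- effect_model(re_warming = 0, cumulative_slope = 0, noise_sd = 0,
                      acute_jump = 0)
  s <- generate_study(tiny_design(1, 3), eff, seed = 5)
  # BS0 and BS1 identical per horse and repetition
  for (r in 1:3) {
    f0 <- s$images$field[[which(s$images$re == r & s$images$bs == 0)]]
    f1 <- s$images$field[[which(s$images$re == r & s$images$bs == 1)]]
    expect_identical(f0, f1)
  }
  # all biomarker series flat
  spread <- dplyr::summarise(
    dplyr::group_by(tidyr::pivot_longer(s$biomarkers, -c(horse, re, bs)),
                    name),
    d = diff(range(value))
  )
  expect_true(all(spread$d == 0))
})

test_that("post-exercise fields warm the muscle regions and clip to camera range", {
  d <- tiny_design(1, 4)
  eff <- effect_model()
  set.seed(9)
  masks <- default_roi_masks(d$image_height, d$image_width)
  off <- list(temp = 0, latent = 0)
  f0 <- generate_temperature_field(d, eff, 1, 3, 0, horse_offsets = off,
                                   masks = masks)
  f1 <- generate_temperature_field(d, eff, 1, 3, 1, horse_offsets = off,
                                   masks = masks)
  for (k in c(1, 3, 4)) {
    expect_gt(mean(f1[masks == k]), mean(f0[masks == k]))
  }
  # BS1 muscle regions are more heterogeneous than BS0
  expect_gt(var(f1[masks == 3]), var(f0[masks == 3]))

  # amplitudes beyond the camera range are clipped at 50
  hot <- effect_model(baseline_temp = 49, re_warming = 30, noise_sd = 0)
  fh <- generate_temperature_field(d, hot, 1, 2, 1, horse_offsets = off,
                                   masks = masks)
  expect_lte(max(fh), 50)
  expect_equal(max(fh), 50)
})

test_that("bs0 field with zero noise is the deterministic baseline surface", {
  d <- tiny_design()
  eff <- effect_model(noise_sd = 0)
  eff$gradient_amp <- 0
  off <- list(temp = 0, latent = 0)
  f <- generate_temperature_field(d, eff, 1, 1, 0, horse_offsets = off)
  expect_equal(unique(as.vector(f)), eff$baseline_temp)
})

test_that("field generation validates indices", {
  d <- tiny_design(2, 3)
  expect_error(generate_temperature_field(d, effect_model(), 3, 1, 0),
               "out-of-range")
  expect_error(generate_temperature_field(d, effect_model(), 1, 4, 0),
               "out-of-range")
  expect_error(generate_temperature_field(d, effect_model(), 1, 1, 2),
               "out-of-range")
})

test_that("noise-free coupled biomarkers are exactly linear in repetition", {
  eff <- effect_model(noise_sd = 0)
  d <- study_design()
  tab <- biomarker_reference()
  b <- tab$bs1_intercept[tab$biomarker == "CPK"]
  s <- eff$cumulative_slope[["CPK"]]
  off <- setNames(rep(0, nrow(tab)), tab$biomarker)
  for (re in c(1, 4, 6)) {
    row <- generate_biomarker_panel(d, eff, 1, re, 1, horse_offsets = off)
    expect_equal(row$CPK, b + s * re)
  }
})

test_that("lactate draws are floored at the 1.0 mmol/L detection limit", {
  tab <- biomarker_reference()
  tab$bs0_mean[tab$biomarker == "LAC"] <- 0.2   # force sub-limit draws
  eff <- effect_model(noise_sd = 0, biomarker_table = tab)
  off <- setNames(rep(0, nrow(tab)), tab$biomarker)
  row <- generate_biomarker_panel(study_design(), eff, 1, 1, 0,
                                  horse_offsets = off)
  expect_equal(row$LAC, 1.0)
  # and every panel value is positive under defaults
  set.seed(11)
  s <- generate_study(tiny_design(3, 2), effect_model(noise_sd = 2), seed = 3)
  vals <- as.matrix(s$biomarkers[, -(1:3)])
  expect_true(all(vals > 0))
  expect_true(all(s$biomarkers$LAC >= 1.0))
})

test_that("invalid designs and effects are rejected", {
  expect_error(study_design(n_horses = 0), "invalid design")
  expect_error(study_design(n_re = 1), "invalid design")
  expect_error(study_design(image_height = 0), "invalid design")
  expect_error(effect_model(noise_sd = -1), "noise_sd")
  expect_error(effect_model(re_warming = -0.1), "re_warming")
})
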