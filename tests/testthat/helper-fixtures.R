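# Shared fixtures: tiny designs and deterministic test images.

tiny_design <- function(n_horses = 1, n_re = 2) {
  study_design(
    n_horses = n_horses, n_re = n_re,
    image_height = 48, image_width = 64
  )
}

small_design <- function(n_horses = 12, n_re = 6) {
  study_design(
    n_horses = n_horses, n_re = n_re,
    image_height = 60, image_width = 80
  )
}

# random quantized channel image (integer levels 1..n_levels)
random_channel <- function(h = 12, w = 12, n_levels = 4) {
  m <- matrix(sample.int(n_levels, h * w, replace = TRUE), h, w)
  storage.mode(m) <- "integer"
  m
}

# random region mask with guaranteed interior mass
random_mask <- function(h = 12, w = 12, density = 0.75) {
  m <- matrix(runif(h * w) < density, h, w)
  m[4:(h - 3), 4:(w - 3)] <- TRUE
  m
}

fast_families <- c("HS", "GM", "AM", "HOG", "GRLM")

fast_config <- function(...) {
  pipeline_config(texture = list(families = fast_families), ...)
}
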