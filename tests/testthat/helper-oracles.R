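# Independent brute-force oracles: naive loop/enumeration implementations
# of every feature family, used to cross-check the vectorized package code.
# They share only the definitional conventions (bin widths, offsets, the
# minimum-norm convention), never the implementation path.

oracle_moments <- function(x) {
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / length(x)
  if (v == 0) return(c(Mean = m, Variance = 0, Skewness = 0, Kurtosis = 0))
  c(
    Mean = m, Variance = v,
    Skewness = sum((x - m)^3) / length(x) / v^(3 / 2),
    Kurtosis = sum((x - m)^4) / length(x) / v^2 - 3
  )
}

oracle_hist <- function(values, roi, n_levels, wide_bin = 10) {
  x <- sort(values[roi])
  N <- length(x)
  counts <- vapply(seq_len(n_levels), function(g) sum(x == g), numeric(1))
  perc <- function(q) {
    cum <- 0
    for (g in seq_len(n_levels)) {
      cum <- cum + counts[g]
      if (cum / N >= q - 1e-12) return(g)
    }
    n_levels
  }
  n_wide <- (n_levels - 1) %/% wide_bin + 1
  wide <- vapply(seq_len(n_wide), function(b) {
    sum(x >= (b - 1) * wide_bin + 1 & x <= b * wide_bin)
  }, numeric(1))
  c(
    Area = N, oracle_moments(x),
    Perc01 = perc(0.01), Perc10 = perc(0.10), Perc50 = perc(0.50),
    Perc90 = perc(0.90), Perc99 = perc(0.99),
    Domn01 = which.max(counts),
    Domn10 = (which.max(wide) - 1) * wide_bin + 1,
    Maxm01 = max(counts) / N, Maxm10 = max(wide) / N
  )
}

# interior pixel: mask true at the pixel and its 4 neighbors (inside image)
oracle_interior <- function(roi, r, c) {
  h <- nrow(roi); w <- ncol(roi)
  r > 1 && r < h && c > 1 && c < w &&
    roi[r, c] && roi[r - 1, c] && roi[r + 1, c] && roi[r, c - 1] && roi[r, c + 1]
}

oracle_gradient_mags <- function(values, roi) {
  mags <- c(); gxs <- c(); gys <- c()
  for (r in seq_len(nrow(values))) {
    for (c in seq_len(ncol(values))) {
      if (oracle_interior(roi, r, c)) {
        gx <- (values[r, c + 1] - values[r, c - 1]) / 2
        gy <- (values[r + 1, c] - values[r - 1, c]) / 2
        gxs <- c(gxs, gx); gys <- c(gys, gy)
        mags <- c(mags, sqrt(gx^2 + gy^2))
      }
    }
  }
  list(mag = mags, gx = gxs, gy = gys)
}

oracle_gradient <- function(values, roi) {
  g <- oracle_gradient_mags(values, roi)
  c(
    Area = length(g$mag), oracle_moments(g$mag),
    NonZeros = sum(g$mag > 0) / length(g$mag)
  )
}

oracle_hog <- function(values, roi) {
  g <- oracle_gradient_mags(values, roi)
  out <- setNames(numeric(8), paste0("O8b", 0:7))
  for (i in seq_along(g$mag)) {
    if (g$mag[i] == 0) next
    ang <- atan2(g$gy[i], g$gx[i]) * 180 / pi
    while (ang < 0) ang <- ang + 180
    while (ang >= 180) ang <- ang - 180
    b <- min(floor(ang / 22.5) + 1, 8)
    out[b] <- out[b] + g$mag[i]
  }
  if (sum(out) > 0) out <- out / sum(out)
  out
}

oracle_ar <- function(values, roi) {
  X <- NULL; y <- c()
  h <- nrow(values); w <- ncol(values)
  for (r in 2:h) {
    for (c in 2:(w - 1)) {
      if (roi[r, c] && roi[r, c - 1] && roi[r - 1, c - 1] &&
          roi[r - 1, c] && roi[r - 1, c + 1]) {
        X <- rbind(X, c(values[r, c - 1], values[r - 1, c - 1],
                        values[r - 1, c], values[r - 1, c + 1]))
        y <- c(y, values[r, c])
      }
    }
  }
  if (is.null(X)) stop("no eligible pixels")
  theta <- as.numeric(MASS::ginv(X) %*% y)
  resid <- y - as.numeric(X %*% theta)
  c(setNames(theta, paste0("Teta", 1:4)), Sigma = sqrt(mean(resid^2)))
}

# direction step (dr, dc) for run/pair enumeration
oracle_step <- function(direction) {
  switch(as.character(direction),
    "0" = c(0, 1), "90" = c(1, 0), "45" = c(-1, 1), "135" = c(1, 1)
  )
}

oracle_glrlm_dir <- function(values, roi, direction, n_levels) {
  st <- oracle_step(direction)
  h <- nrow(values); w <- ncol(values)
  p <- matrix(0, n_levels, max(h, w))
  inside <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w
  for (r0 in seq_len(h)) {
    for (c0 in seq_len(w)) {
      # start of a maximal run: previous step pixel differs or is outside
      rp <- r0 - st[1]; cp <- c0 - st[2]
      if (!roi[r0, c0]) next
      prev_same <- inside(rp, cp) && roi[rp, cp] &&
        values[rp, cp] == values[r0, c0]
      if (prev_same) next
      len <- 1
      r <- r0 + st[1]; c <- c0 + st[2]
      while (inside(r, c) && roi[r, c] && values[r, c] == values[r0, c0]) {
        len <- len + 1
        r <- r + st[1]; c <- c + st[2]
      }
      p[values[r0, c0], len] <- p[values[r0, c0], len] + 1
    }
  }
  p
}

oracle_glrlm <- function(values, roi, n_levels) {
  np <- sum(roi)
  per <- sapply(c("0", "45", "90", "135"), function(d) {
    p <- oracle_glrlm_dir(values, roi, d, n_levels)
    nr <- sum(p)
    sr <- 0; lr <- 0
    for (i in seq_len(nrow(p))) {
      for (l in seq_len(ncol(p))) {
        sr <- sr + p[i, l] / l^2
        lr <- lr + p[i, l] * l^2
      }
    }
    c(
      RLNonUni = sum(colSums(p)^2) / nr,
      GLevNonUn = sum(rowSums(p)^2) / nr,
      LngREmph = lr / nr, ShrtREmp = sr / nr,
      Fraction = nr / np,
      MRLNonUni = sum(colSums(p)^2) / nr^2,
      MGLevNonUn = sum(rowSums(p)^2) / nr^2
    )
  })
  rowMeans(per)
}

oracle_glcm_counts <- function(values, roi, direction, d, n_levels) {
  st <- oracle_step(direction) * d
  h <- nrow(values); w <- ncol(values)
  C <- matrix(0, n_levels, n_levels)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + st[1]; c2 <- c + st[2]
      if (roi[r, c] && r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
          roi[r2, c2]) {
        C[values[r, c], values[r2, c2]] <- C[values[r, c], values[r2, c2]] + 1
      }
    }
  }
  C
}

oracle_haralick <- function(C, log_base) {
  P <- C / sum(C)
  G <- nrow(P)
  lg <- function(x) if (x > 0) log(x, base = log_base) else 0
  mux <- 0; muy <- 0
  for (i in 1:G) for (j in 1:G) { mux <- mux + i * P[i, j]; muy <- muy + j * P[i, j] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    sx2 <- sx2 + (i - mux)^2 * P[i, j]; sy2 <- sy2 + (j - muy)^2 * P[i, j]
  }
  asm <- 0; con <- 0; cor <- 0; ssq <- 0; idm <- 0; ent <- 0
  for (i in 1:G) for (j in 1:G) {
    asm <- asm + P[i, j]^2
    con <- con + (i - j)^2 * P[i, j]
    cor <- cor + i * j * P[i, j]
    ssq <- ssq + (i - mux)^2 * P[i, j]
    idm <- idm + P[i, j] / (1 + (i - j)^2)
    ent <- ent - P[i, j] * lg(P[i, j])
  }
  # degenerate marginals give exactly-zero variance up to accumulation
  # fuzz; the convention is correlation 0
  cor <- if (sx2 > 1e-12 && sy2 > 1e-12) {
    (cor - mux * muy) / sqrt(sx2 * sy2)
  } else 0
  psum <- numeric(2 * G); pdif <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  savg <- 0; for (k in 2:(2 * G)) savg <- savg + k * psum[k]
  sent <- 0; for (k in 2:(2 * G)) sent <- sent - psum[k] * lg(psum[k])
  svar <- 0; for (k in 2:(2 * G)) svar <- svar + (k - savg)^2 * psum[k]
  davg <- 0; for (k in 0:(G - 1)) davg <- davg + k * pdif[k + 1]
  dvar <- 0; for (k in 0:(G - 1)) dvar <- dvar + (k - davg)^2 * pdif[k + 1]
  dent <- 0; for (k in 0:(G - 1)) dent <- dent - pdif[k + 1] * lg(pdif[k + 1])
  c(
    Area = sum(C), AngScMom = asm, Contrast = con, Correlat = cor,
    SumOfSqs = ssq, InvDefMom = idm, SumAverg = savg, SumEntrp = sent,
    SumVarnc = svar, Entropy = ent, DifVarnc = dvar, DifEntrp = dent
  )
}

oracle_glcm <- function(values, roi, n_levels, symmetric,
                        distances = 1:9, directions = c(0, 45, 90, 135),
                        log_base = exp(1)) {
  acc <- NULL; noff <- 0
  for (dir in directions) {
    for (d in distances) {
      C <- oracle_glcm_counts(values, roi, dir, d, n_levels)
      if (sum(C) == 0) next
      if (symmetric) C <- C + t(C)
      f <- oracle_haralick(C, log_base)
      acc <- if (is.null(acc)) f else acc + f
      noff <- noff + 1
    }
  }
  if (noff == 0) stop("no valid pairs")
  acc / noff
}

# direct spatial Gabor convolution at every region pixel with full in-image
# support; same kernel definition as the implementation, evaluated naively
oracle_gabor <- function(values, roi, lambda, theta_deg) {
  sigma <- lambda / 2
  R <- ceiling(3 * sigma)
  d <- seq(-R, R)
  env <- outer(d, d, function(dr, dc) exp(-(dr^2 + dc^2) / (2 * sigma^2)))
  th <- theta_deg * pi / 180
  carrier <- outer(d, d, function(dr, dc) {
    exp(1i * 2 * pi * (dc * cos(th) + dr * sin(th)) / lambda)
  })
  k <- env * (carrier - sum(env * carrier) / sum(env))
  k <- k / sum(env)
  h <- nrow(values); w <- ncol(values)
  mags <- c()
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (!roi[r, c]) next
      if (r - R < 1 || r + R > h || c - R < 1 || c + R > w) next
      patch <- values[(r - R):(r + R), (c - R):(c + R)]
      mags <- c(mags, Mod(sum(k * patch)))
    }
  }
  if (!length(mags)) return(NA_real_)
  mean(mags)
}
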