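# Independent brute-force oracles. Deliberately written as plain double
# loops over the defining sums, sharing no code with the package internals.

# Otsu: exhaustive scan of the between-class variance over all thresholds.
brute_otsu <- function(img, levels = 256L) {
  g <- round(as.vector(img) * (levels - 1L) / 255)
  n <- length(g)
  best_k <- NA_integer_; best_s <- -Inf
  mG <- mean(g)
  for (k in 0:(levels - 1L)) {
    c1 <- g[g <= k]; c2 <- g[g > k]
    if (length(c1) == 0L || length(c2) == 0L) s <- 0
    else {
      P1 <- length(c1) / n; P2 <- length(c2) / n
      s <- P1 * (mean(c1) - mG)^2 + P2 * (mean(c2) - mG)^2
    }
    if (s > best_s + 1e-12) { best_s <- s; best_k <- k }
  }
  list(k = best_k * 255 / (levels - 1L), sigma_b2 = best_s,
       eta = best_s / mean((g - mG)^2))
}

# cross-correlation with replicate padding, one output pixel at a time
brute_correlate <- function(m, k) {
  hy <- (nrow(k) - 1) / 2; hx <- (ncol(k) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k))) {
      ii <- min(max(i + a - 1 - hy, 1), nrow(m))
      jj <- min(max(j + b - 1 - hx, 1), ncol(m))
      acc <- acc + k[a, b] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# scalar evaluation of the Gabor kernel definition, element by element
brute_gabor_kernel <- function(lambda, theta, phi, sigma, gamma, hw) {
  side <- 2 * hw + 1
  out <- matrix(0i, side, side)
  for (r in 1:side) for (c in 1:side) {
    y <- r - hw - 1; x <- c - hw - 1
    xp <- x * cos(theta) + y * sin(theta)
    yp <- y * cos(theta) - x * sin(theta)
    out[r, c] <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) *
      exp(1i * (2 * pi * xp / lambda + phi))
  }
  out
}

brute_raw_moment <- function(img, p, q) {
  acc <- 0
  for (x in seq_len(nrow(img))) for (y in seq_len(ncol(img)))
    acc <- acc + x^p * y^q * img[x, y]
  acc
}

brute_central_moment <- function(img, p, q) {
  m00 <- brute_raw_moment(img, 0, 0)
  xb <- brute_raw_moment(img, 1, 0) / m00
  yb <- brute_raw_moment(img, 0, 1) / m00
  acc <- 0
  for (x in seq_len(nrow(img))) for (y in seq_len(ncol(img)))
    acc <- acc + (x - xb)^p * (y - yb)^q * img[x, y]
  acc
}

# binary dilation/erosion with an arbitrary structuring element (1s mark
# the element; origin at its center); out-of-canvas treated as background.
brute_dilate <- function(m, se) {
  hy <- (nrow(se) - 1) / 2; hx <- (ncol(se) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    hit <- 0
    for (a in seq_len(nrow(se))) for (b in seq_len(ncol(se))) {
      if (se[a, b] == 0) next
      ii <- i + a - 1 - hy; jj <- j + b - 1 - hx
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
          m[ii, jj] == 1) hit <- 1
    }
    out[i, j] <- hit
  }
  out
}

brute_erode <- function(m, se) {
  hy <- (nrow(se) - 1) / 2; hx <- (ncol(se) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ok <- 1
    for (a in seq_len(nrow(se))) for (b in seq_len(ncol(se))) {
      if (se[a, b] == 0) next
      ii <- i + a - 1 - hy; jj <- j + b - 1 - hx
      if (!(ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
            m[ii, jj] == 1)) ok <- 0
    }
    out[i, j] <- ok
  }
  out
}

# scalar per-pixel HSI reference
brute_hsi_pixel <- function(R, G, B) {
  I <- (R + G + B) / 3
  S <- if (R + G + B == 0) 0 else 1 - 3 * min(R, G, B) / (R + G + B)
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  if (den == 0) H <- 0
  else {
    th <- acos(min(1, max(-1, 0.5 * ((R - G) + (R - B)) / den)))
    H <- if (G >= B) th else 2 * pi - th
    if (H >= 2 * pi) H <- 0
  }
  c(h = H, s = S, i = I)
}

# wrap a single pixel into a minimal valid RGB image
pixel_image <- function(rgb, side = 16L) {
  array(rep(rgb, each = side * side), dim = c(side, side, 3L))
}

# nearest-neighbor image rotation about the centroid (for invariance tests)
nn_rotate <- function(img, angle, side = NULL) {
  if (is.null(side)) side <- max(dim(img)) * 2L
  out <- matrix(0, side, side)
  cx <- (nrow(img) + 1) / 2; cy <- (ncol(img) + 1) / 2
  ox <- (side + 1) / 2; oy <- (side + 1) / 2
  for (i in seq_len(side)) for (j in seq_len(side)) {
    # inverse map: rotate output coordinate back into the source frame
    dx <- i - ox; dy <- j - oy
    sx <- round(cx + dx * cos(-angle) - dy * sin(-angle))
    sy <- round(cy + dx * sin(-angle) + dy * cos(-angle))
    if (sx >= 1 && sx <= nrow(img) && sy >= 1 && sy <= ncol(img))
      out[i, j] <- img[sx, sy]
  }
  out
}

# centered ellipse intensity fixture
ellipse_image <- function(side = 64L, a = 22, b = 13, value = 200) {
  x <- matrix(seq_len(side), side, side) - (side + 1) / 2
  y <- matrix(seq_len(side), side, side, byrow = TRUE) - (side + 1) / 2
  ((x / a)^2 + (y / b)^2 <= 1) * value
}
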