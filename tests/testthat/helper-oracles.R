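# Independent reference implementations and fixture builders used across
# the suite.  Oracles here are deliberately written as plain nested loops,
# separate from the package's vectorized code paths.

# Reference SNIP baseline: explicit loops, explicit per-pass copy.
brute_snip <- function(values, max_window) {
  n <- length(values)
  v <- values
  y <- v
  for (p in seq_len(max_window)) {
    ynew <- y
    for (i in seq_len(n)) {
      il <- i - p
      ir <- i + p
      # out-of-range neighbors: odd extension of the input sequence,
      # floored at the boundary value
      left <- if (il >= 1) y[il] else max(2 * v[1] - v[2 - il], v[1])
      right <- if (ir <= n) y[ir] else max(2 * v[n] - v[2 * n - ir], v[n])
      m <- (left + right) / 2
      if (m < y[i]) ynew[i] <- m
    }
    y <- ynew
  }
  y
}

# Sum of squared orthogonal distances of a point cloud to the line through
# `centroid` with direction `dir` (unit vector).
orth_ss <- function(points, centroid, dir) {
  centered <- sweep(points, 2, centroid)
  proj <- centered %*% dir
  sum(centered^2) - sum(proj^2)
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice), for
# brute-force comparison against the fitted principal axis.
sphere_grid <- function(n = 4000) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Noise-free two-tone gray series: `n` positions with a darkness band.
square_wave_series <- function(n = 200, band = c(70, 130),
                               light = 0.7, dark = 0.3) {
  colors <- matrix(light, n, 3)
  colors[(band[1] + 1):band[2], ] <- dark
  color_series(colors)
}

# Constant-color image with an optional right half in a second color.
flat_image <- function(h, w, color, color_right = NULL) {
  img <- array(rep(color, each = h * w), dim = c(h, w, 3))
  if (!is.null(color_right)) {
    for (ch in 1:3) img[, (w %/% 2 + 1):w, ch] <- color_right[ch]
  }
  img
}
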