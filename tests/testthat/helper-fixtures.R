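# Shared test fixtures and independent mini-oracles.

# Independent piecewise-linear interpolation oracle (bracketing search, no
# approx()).
pl_interp_oracle <- function(x, y, xq) {
  vapply(xq, function(q) {
    if (q <= x[1]) return(y[1])
    if (q >= x[length(x)]) return(y[length(y)])
    i <- max(which(x <= q))
    if (x[i] == q) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (q - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# Rank-based AUROC of score as a classifier of label (TRUE = positive).
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Independent exhaustive NCC registration oracle using stats::cor on the
# overlap, structured differently from the package implementation.
register_oracle <- function(ref, moving, max_shift) {
  h <- nrow(ref); w <- ncol(ref)
  best <- c(NA, NA); best_s <- -Inf
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      ys <- intersect(seq_len(h), seq_len(h) - dy)
      xs <- intersect(seq_len(w), seq_len(w) - dx)
      a <- as.vector(ref[ys, xs])
      b <- as.vector(moving[ys + dy, xs + dx])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      s <- stats::cor(a, b)
      if (s > best_s + 1e-12) {
        best_s <- s
        best <- c(dy, dx)
      }
    }
  }
  list(dy = best[1], dx = best[2], score = best_s)
}

# A tiny two-band band set on a coarse grid, for algebraic checks.
toy_bandset <- function() {
  band_set("toy", c(500, 518), c(20, 20), c(0, 1), pattern = 1L)
}

# Smooth pseudo-random test image (sum of a few sinusoids), deterministic.
smooth_image <- function(h, w, seed = 1) {
  withr::with_seed(seed, {
    y <- seq_len(h); x <- seq_len(w)
    img <- outer(sin(y / 3.1), cos(x / 4.7)) +
      0.5 * outer(cos(y / 7.3 + 1), sin(x / 2.9)) +
      matrix(stats::rnorm(h * w, sd = 0.05), h, w)
    img - min(img)
  })
}

# Measured tile spectra = chart divided by a known factor (the
# injection-recovery protocol for the intensity correction).
attenuated_chart_spectra <- function(chart, factor, corrupt_above_nm = NULL,
                                     corrupt_gain = 10) {
  out <- lapply(chart$tile_names, function(t) {
    v <- chart$reflectance[t, ] / factor
    if (!is.null(corrupt_above_nm)) {
      sel <- chart$grid > corrupt_above_nm
      v[sel] <- v[sel] * corrupt_gain
    }
    spectral_curve(chart$grid, v)
  })
  names(out) <- chart$tile_names
  out
}
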