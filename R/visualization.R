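# CIE 1931 2-degree color matching functions, analytic multi-lobe Gaussian
# fits (Wyman, Sloan & Shirley 2013). Accurate to about 1% — ample for
# sampling at narrow band centers.
cie_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 2-degree color matching functions
#' @param wavelength_nm Wavelengths in nm.
#' @return Matrix with columns `x`, `y`, `z`.
#' @export
cie_cmf <- function(wavelength_nm) {
  l <- wavelength_nm
  xb <- 1.056 * cie_gauss(l, 599.8, 37.9, 31.0) +
        0.362 * cie_gauss(l, 442.0, 16.0, 26.7) -
        0.065 * cie_gauss(l, 501.1, 20.4, 26.2)
  yb <- 0.821 * cie_gauss(l, 568.8, 46.9, 40.5) +
        0.286 * cie_gauss(l, 530.9, 16.3, 31.1)
  zb <- 1.217 * cie_gauss(l, 437.0, 11.8, 36.0) +
        0.681 * cie_gauss(l, 459.0, 26.0, 13.8)
  cbind(x = pmax(xb, 0), y = pmax(yb, 0), z = pmax(zb, 0))
}

# linear sRGB from XYZ (IEC 61966-2-1 primaries, D65)
xyz_to_srgb_matrix <- function() {
  matrix(c(3.2406, -1.5372, -0.4986,
           -0.9689, 1.8758, 0.0415,
           0.0557, -0.2040, 1.0570), nrow = 3L, byrow = TRUE)
}

srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Render a reflectance cube as an RGB image
#'
#' Classical RGB reconstruction with the CIE 1931 color matching functions:
#' per pixel, tristimulus values are the band-center samples of reflectance
#' times an equal-energy illuminant times the CMFs, combined with trapezoid
#' weights over the (uneven) band spacing; XYZ maps to linear sRGB and the
#' channels are white-balanced so a unit-reflectance pixel is exactly
#' neutral, then gamma-encoded and clipped to \[0, 1\] (clip fraction
#' reported).
#'
#' @param cube A [band_cube()] in reflectance units with at least 3 bands
#'   spanning at least 100 nm of the 400-700 nm range.
#' @param encode Gamma-encode the output (`FALSE` returns linear values,
#'   clipped).
#' @return An `rgb_image`: h x w x 3 array in \[0, 1\] with attributes
#'   `color_space` and `clip_fraction`.
#' @export
cube_to_rgb <- function(cube, encode = TRUE) {
  if (cube$unit != "reflectance") {
    stop("RGB rendering expects a reflectance cube", call. = FALSE)
  }
  centers <- cube$bandset$center_nm
  vis <- which(centers >= 400 & centers <= 700)
  if (length(vis) < 3L || diff(range(centers[vis])) < 100) {
    stop("need >= 3 bands spanning >= 100 nm of 400-700 nm", call. = FALSE)
  }
  lam <- centers[vis]
  # trapezoid weights on the uneven band-center grid
  wt <- numeric(length(lam))
  dl <- diff(lam)
  wt[1] <- dl[1] / 2
  wt[length(lam)] <- dl[length(dl)] / 2
  if (length(lam) > 2L) {
    wt[2:(length(lam) - 1L)] <- (dl[-length(dl)] + dl[-1]) / 2
  }
  cmf <- cie_cmf(lam)                      # nbands x 3
  weights <- cmf * wt                      # equal-energy illuminant = 1
  d <- dim(cube$data)
  m <- cube_to_matrix(cube)[, vis, drop = FALSE]
  m[!is.finite(m)] <- 0
  xyz <- m %*% weights                     # pixels x 3
  xyz_white <- colSums(weights)            # unit-reflectance pixel
  rgb_lin <- xyz %*% t(xyz_to_srgb_matrix())
  white_lin <- as.vector(xyz_to_srgb_matrix() %*% xyz_white)
  rgb_lin <- sweep(rgb_lin, 2L, white_lin, "/")
  clip_fraction <- mean(rgb_lin < 0 | rgb_lin > 1)
  out <- if (encode) srgb_encode(pmin(pmax(rgb_lin, 0), 1)) else
    pmin(pmax(rgb_lin, 0), 1)
  img <- array(0, dim = c(d[2], d[3], 3L))
  for (ch in 1:3) img[, , ch] <- matrix(out[, ch], d[2], d[3])
  structure(img, class = "rgb_image",
            color_space = if (encode) "sRGB" else "linear",
            clip_fraction = clip_fraction)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d (%s), %.2f%% clipped\n", d[1], d[2],
              attr(x, "color_space"), 100 * attr(x, "clip_fraction")))
  invisible(x)
}

#' Principal component basis of a cube's band covariance
#'
#' Eigen-decomposition of the band-covariance of the mean-centered pixel
#' spectra, with a deterministic sign convention (the largest-magnitude
#' entry of each basis vector is positive). Components beyond the data rank
#' are flagged.
#'
#' @param cube A [band_cube()].
#' @param mask Optional logical matrix restricting the pixels used to fit
#'   the basis (scores are still computed for all pixels).
#' @return A `pca_basis`: `basis` (bands x N, orthonormal columns ordered by
#'   decreasing explained variance), `variance`, `var_explained`, `mean`,
#'   `scores` (h x w x N array of coefficients), `rank`.
#' @export
pca_basis <- function(cube, mask = NULL) {
  d <- dim(cube$data)
  nb <- d[1]
  m <- cube_to_matrix(cube)
  fit_rows <- if (is.null(mask)) seq_len(nrow(m)) else which(as.vector(mask))
  if (length(fit_rows) < nb + 1L) {
    stop("need at least N+1 pixels to fit an N-band basis", call. = FALSE)
  }
  mu <- colMeans(m[fit_rows, , drop = FALSE])
  centered <- sweep(m[fit_rows, , drop = FALSE], 2L, mu)
  cv <- stats::cov(centered)
  eg <- eigen(cv, symmetric = TRUE)
  basis <- eg$vectors
  lambda <- pmax(eg$values, 0)
  for (i in seq_len(nb)) {
    j <- which.max(abs(basis[, i]))
    if (basis[j, i] < 0) basis[, i] <- -basis[, i]
  }
  rank <- sum(lambda > max(lambda) * 1e-12)
  scores_m <- sweep(m, 2L, mu) %*% basis
  scores <- array(0, dim = c(d[2], d[3], nb))
  for (i in seq_len(nb)) scores[, , i] <- matrix(scores_m[, i], d[2], d[3])
  structure(list(basis = basis, variance = lambda,
                 var_explained = lambda / sum(lambda), mean = mu,
                 scores = scores, rank = rank,
                 center_nm = cube$bandset$center_nm),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> %d components (rank %d); leading explains %.1f%%\n",
              length(x$variance), x$rank, 100 * x$var_explained[1]))
  invisible(x)
}

#' Enhancement specification
#'
#' The diagonal weighting matrix `W` (nonzero only on bands inside the
#' selected wavelength interval), the number `m` of leading principal
#' components excluded, and the enhancement gain.
#'
#' @param interval_nm Length-2 wavelength window whose bands are enhanced.
#' @param gain Magnification applied to the selected bands.
#' @param m Number of leading components to exclude: an integer, or
#'   `"auto"` = the smallest m whose leading components explain at least
#'   `var_threshold` of the variance.
#' @param var_threshold Variance fraction for `m = "auto"`.
#' @return An `enhancement_spec`.
#' @export
enhancement_spec <- function(interval_nm, gain = 5, m = "auto",
                             var_threshold = 0.95) {
  stopifnot(length(interval_nm) == 2L, interval_nm[1] <= interval_nm[2],
            gain >= 0)
  structure(list(interval_nm = as.numeric(interval_nm), gain = gain, m = m,
                 var_threshold = var_threshold),
            class = "enhancement_spec")
}

resolve_m <- function(basis, spec) {
  if (identical(spec$m, "auto")) {
    cum <- cumsum(basis$var_explained)
    m <- which(cum >= spec$var_threshold)[1]
    if (is.na(m)) m <- length(basis$var_explained)
    m
  } else {
    as.integer(spec$m)
  }
}

#' PCA minor-component enhancement map
#'
#' Implements the weighted minor-component reconstruction
#' `J = W sum_{i = m+1}^{N} gamma_i A_i`: per pixel, the residual spectrum
#' carried by the minor components is weighted by the diagonal matrix `W`
#' (gain on the bands inside the selected interval, zero elsewhere), summed
#' over bands to a scalar, and the map is min-max normalized to \[0, 1\].
#' Subtle spectral differences confined to the selected interval — too small
#' to survive in the leading components — become visible.
#'
#' @param basis A [pca_basis()].
#' @param spec An [enhancement_spec()].
#' @return 2-D enhancement map in \[0, 1\] with attributes `m` and
#'   `w_diagonal`. `W = 0` or `m = N` yield an all-zero map (with a warning
#'   for `m >= N`).
#' @export
enhance <- function(basis, spec) {
  nb <- length(basis$variance)
  m <- resolve_m(basis, spec)
  stopifnot(m >= 0, m <= nb)
  w <- ifelse(basis$center_nm >= spec$interval_nm[1] &
              basis$center_nm <= spec$interval_nm[2], spec$gain, 0)
  hw <- dim(basis$scores)[1:2]
  if (m >= nb) {
    warning("m >= N: empty minor-component sum, zero enhancement map")
    return(structure(matrix(0, hw[1], hw[2]), m = m, w_diagonal = w))
  }
  idx <- (m + 1L):nb
  sc <- matrix(basis$scores, prod(hw), nb)[, idx, drop = FALSE]
  resid <- sc %*% t(basis$basis[, idx, drop = FALSE])   # pixels x bands
  map <- matrix(resid %*% w, hw[1], hw[2])
  rng <- range(map)
  map <- if (diff(rng) < 1e-15) matrix(0, hw[1], hw[2]) else
    (map - rng[1]) / diff(rng)
  structure(map, m = m, w_diagonal = w)
}

#' Add an enhancement map to the blue channel
#'
#' `B' = clip(B + blend * map)`; red and green are unchanged. Highlighted
#' structures appear blue in the rendered scene.
#'
#' @param rgb An `rgb_image`.
#' @param map 2-D map matching the image's spatial size.
#' @param blend Blend factor in \[0, 1\].
#' @return The modified `rgb_image`.
#' @export
add_to_blue <- function(rgb, map, blend = 0.5) {
  stopifnot(blend >= 0, blend <= 1)
  d <- dim(rgb)
  if (!identical(dim(map), d[1:2])) {
    stop("map shape does not match the image", call. = FALSE)
  }
  rgb[, , 3] <- pmin(pmax(rgb[, , 3] + blend * map, 0), 1)
  rgb
}

#' Synthetic two-tissue hypercube
#'
#' A two-region scene for exercising the enhancement pipeline: both regions
#' share a base reflectance spectrum and a dominant per-pixel brightness
#' variation (albedo/shading, the leading PCA mode of real scenes); region B
#' additionally carries a small reflectance bump confined to a wavelength
#' interval. Gaussian noise is added per band.
#'
#' @param bandset Band set for the cube (41-band assembly or any other).
#' @param interval_nm Interval of the region-B contrast.
#' @param contrast Peak extra reflectance of region B inside the interval.
#' @param noise_sd Per-band Gaussian noise SD.
#' @param brightness_sd SD of the per-pixel brightness factor.
#' @param shape Spatial size `c(h, w)`; region B is the right half.
#' @param seed RNG seed.
#' @return List with `cube` (a reflectance [band_cube()]) and `region_b`
#'   (logical mask).
#' @export
simulate_two_tissue_cube <- function(bandset, interval_nm = c(460, 480),
                                     contrast = 0.05, noise_sd = 0.01,
                                     brightness_sd = 0.1,
                                     shape = c(32L, 32L), seed = 1L) {
  h <- shape[1]; w <- shape[2]
  centers <- bandset$center_nm
  base <- 0.35 + 0.2 * sin((centers - min(centers)) /
                           diff(range(centers)) * pi)
  bump <- contrast * exp(-((centers - mean(interval_nm))^2) /
                         (2 * (diff(interval_nm) / 2.355)^2))
  region_b <- matrix(FALSE, h, w)
  region_b[, (w %/% 2 + 1L):w] <- TRUE
  data <- withr::with_seed(as.integer(seed), {
    bright <- 1 + matrix(stats::rnorm(h * w, sd = brightness_sd), h, w)
    arr <- array(0, dim = c(length(centers), h, w))
    for (b in seq_along(centers)) {
      plane <- bright * base[b] + ifelse(region_b, bump[b], 0)
      arr[b, , ] <- plane + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
    }
    arr
  })
  list(cube = band_cube(pmax(data, 0), bandset, "reflectance",
                        provenance = "synthetic_two_tissue"),
       region_b = region_b)
}
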