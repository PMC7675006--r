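#' Reference color chart
#'
#' A 24-tile chart (18 colored + 6 gray-scale tiles) with per-tile reference
#' reflectance and per-wavelength standard deviation on the 390-1000 nm,
#' 10 nm grid — the ground truth used to fit the intensity-correction scalar
#' and to validate reconstructed spectra.
#'
#' @param tile_names Character vector of 24 tile labels.
#' @param grid Wavelength grid (must be 390-1000 nm at 10 nm steps).
#' @param reflectance 24 x 62 matrix of reflectance in \[0, 1\] (rows = tiles).
#' @param sd 24 x 62 matrix of nonnegative standard deviations.
#' @return An object of class `reference_chart`.
#' @export
reference_chart <- function(tile_names, grid, reflectance, sd) {
  if (length(tile_names) != 24L) stop("a reference chart has exactly 24 tiles",
                                      call. = FALSE)
  if (!isTRUE(all.equal(grid, chart_grid()))) {
    stop("chart grid must be 390-1000 nm at 10 nm steps (62 samples)",
         call. = FALSE)
  }
  reflectance <- as.matrix(reflectance)
  sd <- as.matrix(sd)
  stopifnot(dim(reflectance) == c(24L, length(grid)),
            dim(sd) == c(24L, length(grid)))
  if (any(reflectance < 0) || any(reflectance > 1)) {
    stop("chart reflectance must lie in [0, 1]", call. = FALSE)
  }
  if (any(sd < 0)) stop("chart sd must be nonnegative", call. = FALSE)
  rownames(reflectance) <- rownames(sd) <- tile_names
  structure(list(tile_names = tile_names, grid = grid,
                 reflectance = reflectance, sd = sd),
            class = "reference_chart")
}

#' @export
print.reference_chart <- function(x, ...) {
  cat(sprintf("<reference_chart> 24 tiles on %g-%g nm / 10 nm; sd in [%g, %g]\n",
              min(x$grid), max(x$grid), min(x$sd), max(x$sd)))
  invisible(x)
}

#' Reflectance curve of one chart tile
#' @param chart A [reference_chart()].
#' @param tile Tile name or index.
#' @return A [spectral_curve()].
#' @export
chart_tile_curve <- function(chart, tile) {
  spectral_curve(chart$grid, chart$reflectance[tile, ])
}

# Fixed gray-scale levels (neutral tile reflectances) and tile names.
.gray_levels <- c(0.90, 0.59, 0.36, 0.19, 0.09, 0.03)
.gray_names <- c("white 9.5", "neutral 8", "neutral 6.5", "neutral 5",
                 "neutral 3.5", "black 2")
.color_names <- c("dark skin", "light skin", "blue sky", "foliage",
                  "blue flower", "bluish green", "orange", "purplish blue",
                  "moderate red", "purple", "yellow green", "orange yellow",
                  "blue", "green", "red", "yellow", "magenta", "cyan")

#' Generate a synthetic 24-tile reference chart
#'
#' Synthetic stand-in with the structure of a classic 24-tile color checker:
#' 18 colored tiles are smooth random mixtures of 2-4 Gaussian bumps scaled
#' into \[0.03, 0.95\]; 6 gray tiles are flat at the fixed levels 0.90, 0.59,
#' 0.36, 0.19, 0.09, 0.03. The per-wavelength SD envelope grows smoothly from
#' 0.002 in the visible to 0.11 in the NIR, as reported for
#' spectroradiometer-calibrated charts. Gray tiles are seed-independent;
#' colored tiles vary with the seed.
#'
#' @param seed Integer RNG seed for the colored tiles.
#' @return A [reference_chart()].
#' @examples
#' ch <- make_reference_chart(seed = 1)
#' dim(ch$reflectance)  # 24 x 62
#' @export
make_reference_chart <- function(seed = 1L) {
  grid <- chart_grid()
  n <- length(grid)
  colored <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(18L), function(i) {
      k <- sample(2:4, 1L)
      centers <- stats::runif(k, 390, 1000)
      widths <- stats::runif(k, 35, 120)
      amps <- stats::runif(k, 0.25, 1)
      raw <- rowSums(vapply(seq_len(k), function(j) {
        amps[j] * exp(-((grid - centers[j])^2) / (2 * widths[j]^2))
      }, numeric(n)))
      lo <- stats::runif(1, 0.03, 0.12)
      hi <- stats::runif(1, 0.45, 0.95)
      lo + (raw - min(raw)) / (max(raw) - min(raw)) * (hi - lo)
    }, numeric(n)))
  })
  gray <- matrix(rep(.gray_levels, each = n), nrow = 6L, byrow = TRUE)
  refl <- rbind(colored, gray)
  # SD envelope: ~0.002 below ~650 nm, rising to ~0.11 deep in the NIR
  envelope <- 0.002 + 0.108 / (1 + exp(-(grid - 800) / 55))
  sd <- matrix(rep(envelope, each = 24L), nrow = 24L, byrow = FALSE)
  reference_chart(c(.color_names, .gray_names), grid, refl, sd)
}
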