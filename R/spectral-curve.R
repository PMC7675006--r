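#' Sampled spectral curve
#'
#' The universal carrier for anything sampled over wavelength: tile
#' reflectance, illumination power, sensor band responses. A curve is a pair
#' of equal-length vectors, wavelengths strictly increasing and values
#' nonnegative.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nanometres, strictly
#'   increasing.
#' @param value Numeric vector of nonnegative samples, same length.
#' @return An object of class `spectral_curve`.
#' @examples
#' sc <- spectral_curve(c(400, 500, 600), c(0.1, 0.5, 0.2))
#' curve_at(sc, 450)
#' @export
spectral_curve <- function(wavelength_nm, value) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value)) {
    stop("wavelength_nm and value must have equal length", call. = FALSE)
  }
  if (length(wavelength_nm) < 1L) stop("empty spectral curve", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < -1e-12)) {
    stop("curve values must be finite and nonnegative", call. = FALSE)
  }
  value[value < 0] <- 0
  structure(list(wavelength_nm = wavelength_nm, value = value),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve> %d samples on [%g, %g] nm, values [%g, %g]\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$value), max(x$value)))
  invisible(x)
}

#' @export
length.spectral_curve <- function(x) length(x$wavelength_nm)

#' Evaluate a spectral curve by linear interpolation
#'
#' @param curve A [spectral_curve()].
#' @param wavelength_nm Query wavelengths, all inside the curve's support.
#' @return Numeric vector of interpolated values.
#' @export
curve_at <- function(curve, wavelength_nm) {
  stopifnot(inherits(curve, "spectral_curve"))
  rng <- range(curve$wavelength_nm)
  if (any(wavelength_nm < rng[1] - 1e-9) || any(wavelength_nm > rng[2] + 1e-9)) {
    stop(sprintf("wavelengths outside curve support [%g, %g] nm: extrapolation refused",
                 rng[1], rng[2]), call. = FALSE)
  }
  if (length(curve$wavelength_nm) == 1L) {
    return(rep(curve$value, length(wavelength_nm)))
  }
  stats::approx(curve$wavelength_nm, curve$value, xout = wavelength_nm,
                method = "linear", rule = 1)$y
}

#' Resample a spectral curve onto a new wavelength grid
#'
#' Linear interpolation; exact at shared sample points; refuses to
#' extrapolate outside the curve's support. Resampling onto the curve's own
#' grid is the identity.
#'
#' @inheritParams curve_at
#' @param grid Target wavelength grid (strictly increasing, inside support).
#' @return A [spectral_curve()] on `grid`.
#' @export
resample_curve <- function(curve, grid) {
  v <- curve_at(curve, grid)
  spectral_curve(grid, pmax(v, 0))
}

#' Ideal Gaussian band response
#'
#' Unit-peak Gaussian whose half-maximum crossings are separated by
#' `fwhm_nm` (sigma = fwhm / (2 sqrt(2 ln 2))).
#'
#' @param center_nm Band center wavelength (nm).
#' @param fwhm_nm Full width at half maximum (nm), positive.
#' @param grid Wavelength grid to sample on.
#' @return A [spectral_curve()] on `grid` with peak value 1 at the center.
#' @export
gaussian_band_response <- function(center_nm, fwhm_nm, grid) {
  if (!is.numeric(fwhm_nm) || length(fwhm_nm) != 1L || fwhm_nm <= 0) {
    stop("fwhm_nm must be a positive scalar", call. = FALSE)
  }
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  spectral_curve(grid, exp(-((grid - center_nm)^2) / (2 * sigma^2)))
}

#' Default internal working wavelength grid
#'
#' 390 to 1000 nm at 1 nm: fine enough to resolve the narrowest packaged
#' band (FWHM 4 nm) while covering the reference chart's 390-1000 nm span.
#'
#' @return Numeric vector of wavelengths.
#' @export
working_grid <- function() seq(390, 1000, by = 1)

#' Reference-chart wavelength grid (390-1000 nm at 10 nm, 62 samples)
#' @return Numeric vector of wavelengths.
#' @export
chart_grid <- function() seq(390, 1000, by = 10)
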