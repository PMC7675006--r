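#' Sensor response set
#'
#' Per-band spectral response curves of an instrument on a common wavelength
#' grid, with peak heights at most 1 (relative quantum efficiency times
#' filter transmission).
#'
#' @param bandset A `band_set`.
#' @param grid Common wavelength grid.
#' @param responses Band x wavelength matrix of responses in \[0, 1\], rows in
#'   sorted band order.
#' @return An object of class `sensor_response_set`.
#' @export
sensor_response_set <- function(bandset, grid, responses) {
  responses <- as.matrix(responses)
  stopifnot(nrow(responses) == n_bands(bandset),
            ncol(responses) == length(grid))
  if (any(responses < 0) || any(responses > 1 + 1e-9)) {
    stop("responses must lie in [0, 1]", call. = FALSE)
  }
  structure(list(bandset = bandset, grid = grid, responses = responses),
            class = "sensor_response_set")
}

#' @export
print.sensor_response_set <- function(x, ...) {
  cat(sprintf("<sensor_response_set> %d bands (%s), grid %g-%g nm, peak heights %.3g-%.3g\n",
              n_bands(x$bandset), band_setup(x$bandset), min(x$grid),
              max(x$grid), min(apply(x$responses, 1, max)),
              max(apply(x$responses, 1, max))))
  invisible(x)
}

#' Default secondary response peaks for a band set
#'
#' The NIR mosaic camera's filters show two main response peaks in some
#' bands; by default two of the 25 NIR bands carry an additive secondary
#' Gaussian 150 nm below the primary at 30% of its height. Other setups get
#' none.
#'
#' @param bandset A `band_set`.
#' @return A list of `list(band, center_nm, height)` entries (possibly empty);
#'   `band` is the 1-based sorted band index, `height` is relative to the
#'   primary peak.
#' @export
default_secondary_peaks <- function(bandset) {
  if (!identical(band_setup(bandset), "cam5x5")) return(list())
  picks <- c(17L, 21L)  # bands at 900 and 940 nm
  lapply(picks, function(b) {
    list(band = b, center_nm = bandset$center_nm[b] - 150, height = 0.3)
  })
}

#' Synthesize sensor responses for a band set
#'
#' Gaussian primary response at each packaged band center/FWHM. Peak heights
#' emulate the measured response gaps: about 0.2 for the 16-band visible
#' camera (except sorted band 3 at 0.1), about 0.1 for the 25-band NIR
#' camera, and 1.0 (panchromatic, ideal) for the filter-wheel sensor.
#' Optional additive secondary Gaussian peaks model double-peaked filters.
#'
#' @param bandset A `band_set`.
#' @param secondary_peaks `NULL` for none, `"default"` for
#'   [default_secondary_peaks()], or a list of `list(band, center_nm,
#'   height)` with `height` relative to the primary peak (must be < 1).
#' @param grid Wavelength grid (default [working_grid()]).
#' @return A [sensor_response_set()].
#' @export
make_sensor_responses <- function(bandset, secondary_peaks = NULL,
                                  grid = working_grid()) {
  setup <- band_setup(bandset)
  nb <- n_bands(bandset)
  heights <- switch(setup,
    cam4x4 = { h <- rep(0.2, nb); h[4L] <- 0.1; h },  # sorted band 3 (0-based)
    cam5x5 = rep(0.1, nb),
    rep(1.0, nb))
  if (identical(secondary_peaks, "default")) {
    secondary_peaks <- default_secondary_peaks(bandset)
  }
  resp <- t(vapply(seq_len(nb), function(b) {
    heights[b] * gaussian_band_response(bandset$center_nm[b],
                                        bandset$fwhm_nm[b], grid)$value
  }, numeric(length(grid))))
  for (sp in secondary_peaks) {
    if (sp$height >= 1) {
      stop("secondary peak height must be below the primary peak", call. = FALSE)
    }
    b <- sp$band
    sec <- heights[b] * sp$height *
      gaussian_band_response(sp$center_nm, bandset$fwhm_nm[b], grid)$value
    resp[b, ] <- resp[b, ] + sec
  }
  sensor_response_set(bandset, grid, pmin(resp, 1))
}
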