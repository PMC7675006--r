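#' Instrument band tables
#'
#' The three supported setups and their band definitions (center wavelength,
#' FWHM, sensor position), shipped as a versioned JSON resource:
#'
#' * `filter_wheel` — 19 illumination bands: 400-700 nm every 20 nm
#'   (FWHM 10 nm) plus 750/800/850 nm (FWHM 25 nm).
#' * `cam4x4` — 16-band mosaic snapshot camera, 463-638 nm.
#' * `cam5x5` — 25-band mosaic snapshot camera, 693-966 nm.
#'
#' Bands are listed sorted by center wavelength; for the mosaic cameras the
#' `sensor_index` (row-major position inside the pattern cell, 0-based) is a
#' fixed permutation that does not follow the sorted order, as on the real
#' sensors.
#'
#' @param setup_name One of `"filter_wheel"`, `"cam4x4"`, `"cam5x5"`.
#' @return A `band_set`: a tibble with columns `center_nm`, `fwhm_nm`,
#'   `sensor_index`, `sorted_index` plus attributes `setup` and `pattern`.
#' @examples
#' bs <- load_band_table("cam4x4")
#' nrow(bs)         # 16
#' attr(bs, "pattern")
#' @export
load_band_table <- function(setup_name) {
  path <- system.file("extdata", "band_tables.json", package = "hsical",
                      mustWork = TRUE)
  tables <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)$setups
  if (!setup_name %in% names(tables)) {
    stop(sprintf("unknown setup '%s'; expected one of %s", setup_name,
                 paste(names(tables), collapse = ", ")), call. = FALSE)
  }
  entry <- tables[[setup_name]]
  band_set(setup_name, entry$bands$center_nm, entry$bands$fwhm_nm,
           entry$bands$sensor_index, pattern = entry$pattern)
}

#' Construct a band set
#'
#' @param setup_name Setup label.
#' @param center_nm Band centers (nm), unique.
#' @param fwhm_nm Band FWHMs (nm), positive.
#' @param sensor_index 0-based position of each band on the sensor
#'   (mosaic-cell position or wheel slot); a permutation of `0:(n-1)`.
#' @param pattern Mosaic period (1 for filter-wheel setups).
#' @return A `band_set` tibble sorted by center wavelength.
#' @export
band_set <- function(setup_name, center_nm, fwhm_nm, sensor_index,
                     pattern = 1L) {
  n <- length(center_nm)
  stopifnot(length(fwhm_nm) == n, length(sensor_index) == n)
  if (anyDuplicated(center_nm)) stop("band centers must be unique", call. = FALSE)
  if (any(fwhm_nm <= 0)) stop("fwhm_nm must be positive", call. = FALSE)
  if (!setequal(sensor_index, 0:(n - 1L))) {
    stop("sensor_index must be a permutation of 0:(n-1)", call. = FALSE)
  }
  if (pattern > 1L && pattern^2 < n) {
    stop("pattern^2 must be >= band count for mosaic setups", call. = FALSE)
  }
  ord <- order(center_nm)
  bs <- tibble::tibble(
    center_nm = as.numeric(center_nm)[ord],
    fwhm_nm = as.numeric(fwhm_nm)[ord],
    sensor_index = as.integer(sensor_index)[ord],
    sorted_index = 0:(n - 1L)
  )
  attr(bs, "setup") <- setup_name
  attr(bs, "pattern") <- as.integer(pattern)
  class(bs) <- c("band_set", class(bs))
  bs
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> setup '%s': %d bands, %g-%g nm, pattern %d\n",
              attr(x, "setup"), nrow(x), min(x$center_nm), max(x$center_nm),
              attr(x, "pattern")))
  NextMethod()
}

band_pattern <- function(bandset) attr(bandset, "pattern")
band_setup <- function(bandset) attr(bandset, "setup")
n_bands <- function(bandset) nrow(bandset)

#' Optimal exposure times per setup and illumination
#'
#' Packaged defaults for the five operating points (filter-wheel under
#' xenon; each snapshot camera under xenon or surgical LED). For the
#' filter-wheel setup the time is per wavelength band.
#'
#' @param setup_name Setup label.
#' @param illumination_kind `"xenon"` or `"led"`.
#' @return Exposure time in milliseconds.
#' @export
default_exposure_ms <- function(setup_name, illumination_kind = "xenon") {
  key <- paste(setup_name, illumination_kind, sep = "/")
  tab <- c("filter_wheel/xenon" = 42, "cam4x4/xenon" = 65,
           "cam4x4/led" = 0.5, "cam5x5/xenon" = 110, "cam5x5/led" = 7.5)
  if (!key %in% names(tab)) {
    stop(sprintf("no packaged exposure for '%s'", key), call. = FALSE)
  }
  unname(tab[key])
}
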