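#' Band-indexed image cube
#'
#' The working container along the calibration chain: a band x height x
#' width array with band metadata, a unit tag (`counts` before, `reflectance`
#' after white conversion) and an ordered provenance of applied steps.
#'
#' @param data Band x height x width numeric array.
#' @param bandset A `band_set` with one row per band plane.
#' @param unit `"counts"` or `"reflectance"`.
#' @param provenance Character vector of applied processing steps.
#' @return An object of class `band_cube`.
#' @export
band_cube <- function(data, bandset, unit = c("counts", "reflectance"),
                      provenance = character()) {
  unit <- match.arg(unit)
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[1] != n_bands(bandset)) {
    stop("band dimension must equal the band count", call. = FALSE)
  }
  structure(list(data = data, bandset = bandset, unit = unit,
                 provenance = provenance), class = "band_cube")
}

#' @export
print.band_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<band_cube> %d bands x %d x %d px [%s] (%s)\n  steps: %s\n",
              d[1], d[2], d[3], x$unit, band_setup(x$bandset),
              if (length(x$provenance)) paste(x$provenance, collapse = " -> ")
              else "none"))
  invisible(x)
}

#' @export
dim.band_cube <- function(x) dim(x$data)

cube_note <- function(cube, step) {
  cube$provenance <- c(cube$provenance, step)
  cube
}

#' Cube view of a filter-wheel frame stack
#'
#' The sequential filter-wheel acquisition is already band-planar; this tags
#' it as a counts cube carrying the stack's exposure.
#'
#' @param stack A [frame_stack()].
#' @return A [band_cube()] in counts with an `exposure_ms` attribute.
#' @export
stack_to_cube <- function(stack) {
  out <- band_cube(stack$frames, stack$bandset, "counts",
                   provenance = "stack_assembled")
  attr(out, "exposure_ms") <- stack$exposure_ms
  out
}

cube_exposure <- function(cube) attr(cube, "exposure_ms")

# Pixels-by-bands matrix view (rows = pixels in column-major spatial order).
cube_to_matrix <- function(cube) {
  d <- dim(cube$data)
  t(matrix(cube$data, nrow = d[1]))
}

matrix_to_cube_data <- function(m, h, w) {
  array(t(m), dim = c(ncol(m), h, w))
}

#' Spatial mean spectra of labelled regions
#'
#' Per tile mask: the spatial mean and SD of every band plane — the
#' per-tile measured spectrum used for intensity-correction fitting and
#' chart validation.
#'
#' @param cube A [band_cube()].
#' @param tile_masks Named list of logical matrices matching the cube's
#'   spatial dimensions.
#' @return A tibble with columns `tile`, `wavelength_nm`, `value`, `sd`, `n`.
#' @export
extract_tile_spectra <- function(cube, tile_masks) {
  d <- dim(cube$data)
  rows <- lapply(names(tile_masks), function(nm) {
    mask <- tile_masks[[nm]]
    if (!any(mask)) stop(sprintf("empty mask for tile '%s'", nm), call. = FALSE)
    stopifnot(dim(mask)[1] == d[2], dim(mask)[2] == d[3])
    vals <- vapply(seq_len(d[1]), function(b) {
      px <- cube$data[b, , ][mask]
      c(mean(px, na.rm = TRUE), stats::sd(px, na.rm = TRUE), sum(!is.na(px)))
    }, numeric(3))
    tibble::tibble(tile = nm, wavelength_nm = cube$bandset$center_nm,
                   value = vals[1, ], sd = vals[2, ], n = as.integer(vals[3, ]))
  })
  do.call(rbind, rows)
}
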