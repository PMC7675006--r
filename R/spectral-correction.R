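#' Demosaic a snapshot mosaic frame into a band cube
#'
#' Plane extraction, no interpolation: band `b`'s plane collects the one
#' pixel per pattern cell whose mosaic position carries that band, so the
#' output is `pattern` times smaller in each spatial dimension. Planes are
#' ordered by ascending center wavelength (sorted band order), not by sensor
#' position.
#'
#' @param frame A [mosaic_frame()], or a bare matrix together with `bandset`.
#' @param bandset Required when `frame` is a bare matrix.
#' @return A [band_cube()] in counts carrying the frame's exposure.
#' @export
demosaic <- function(frame, bandset = NULL) {
  if (inherits(frame, "mosaic_frame")) {
    bandset <- frame$bandset
    exposure <- frame$exposure_ms
    img <- frame$pixels
  } else {
    if (is.null(bandset)) stop("bandset required for a bare matrix",
                               call. = FALSE)
    exposure <- NULL
    img <- frame
  }
  p <- band_pattern(bandset)
  h <- nrow(img); w <- ncol(img)
  if (h %% p != 0L || w %% p != 0L) {
    stop("frame dimensions must be multiples of the mosaic pattern",
         call. = FALSE)
  }
  nb <- n_bands(bandset)
  out <- array(NA_real_, dim = c(nb, h %/% p, w %/% p))
  for (b in seq_len(nb)) {
    pos <- bandset$sensor_index[b]
    dy <- pos %/% p; dx <- pos %% p
    out[b, , ] <- img[seq(1L + dy, h, by = p), seq(1L + dx, w, by = p)]
  }
  cube <- band_cube(out, bandset, "counts", provenance = "demosaic")
  if (!is.null(exposure)) attr(cube, "exposure_ms") <- exposure
  cube
}

#' Demosaic a dark reference measured on the mosaic sensor
#'
#' Mean and SD frames are plane-extracted so they match demosaiced cubes.
#'
#' @param dark A `dark_reference` with 2-D mean/SD frames.
#' @param bandset The mosaic `band_set`.
#' @return A `dark_reference` with band x h x w mean and SD arrays.
#' @export
demosaic_dark <- function(dark, bandset) {
  stopifnot(inherits(dark, "dark_reference"), length(dim(dark$mean_frame)) == 2L)
  dark$mean_frame <- demosaic(dark$mean_frame, bandset)$data
  dark$noise_sd <- demosaic(dark$noise_sd, bandset)$data
  dark
}

#' Spectral crosstalk correction matrix
#'
#' The linear operator that maps measured band values (overlapping
#' responses, secondary peaks) to the values nearly ideal narrowband filters
#' would have produced — a deconvolution of the spectral bands. It is
#' computed from the instrument's measured response curves by
#' Tikhonov-regularized least squares against ideal unit-area Gaussian
#' targets at the packaged band centers/FWHMs:
#' `C^T = argmin || (C^T R - T) S ||^2 + ridge ||C^T||^2`
#' where rows of `R` are the (optionally illumination-weighted) measured
#' responses normalized to unit sum, rows of `T` are the normalized targets,
#' and `S` projects onto a basis of smooth spectra (Gaussians of width
#' `basis_sigma_nm` spaced `basis_spacing_nm` across the grid). Fitting the
#' operator's action on smooth spectra — rather than pointwise in wavelength
#' — is what makes narrow secondary peaks correctable by neighboring bands.
#' Because the matrix acts on white-normalized reflectance (where a
#' spectrally flat scene reads 1 in every band), columns of `C` are finally
#' rescaled so a flat input maps to a flat output.
#'
#' @param responses A [sensor_response_set()] of measured band responses.
#' @param target A `band_set` defining the ideal target bands (same count).
#' @param ridge Regularization weight, relative to the mean diagonal of the
#'   response Gram matrix. 0 requests the exact normal-equation solution and
#'   fails with advice if the Gram matrix is singular.
#' @param illumination Optional illumination [spectral_curve()]; when given,
#'   responses and targets are weighted by it before normalization (the
#'   matrix then corrects white-normalized reflectance under that source).
#'   Default `NULL` assumes spectrally flat illumination.
#' @param normalize Rescale columns for flat-in/flat-out behaviour
#'   (disable only for algebraic analyses of the unscaled solution).
#' @param basis_sigma_nm,basis_spacing_nm Width and spacing of the smooth
#'   fitting basis.
#' @return A `correction_matrix` with the band_in x band_out matrix in
#'   `$matrix` (measured spectrum row-vector times matrix = corrected).
#' @export
build_correction_matrix <- function(responses, target, ridge = 1e-4,
                                    illumination = NULL, normalize = TRUE,
                                    basis_sigma_nm = 15,
                                    basis_spacing_nm = 10) {
  stopifnot(inherits(responses, "sensor_response_set"))
  nb <- n_bands(responses$bandset)
  if (n_bands(target) != nb) {
    stop("response and target band counts must be equal", call. = FALSE)
  }
  grid <- responses$grid
  wgt <- if (is.null(illumination)) rep(1, length(grid)) else
    curve_at(illumination, grid)
  R <- responses$responses * rep(wgt, each = nb)
  Tm <- t(vapply(seq_len(nb), function(b) {
    gaussian_band_response(target$center_nm[b], target$fwhm_nm[b],
                           grid)$value * wgt
  }, numeric(length(grid))))
  rs <- rowSums(R)
  ts <- rowSums(Tm)
  if (any(rs <= 0) || any(ts <= 0)) {
    stop("a band response vanishes under the given illumination", call. = FALSE)
  }
  Rn <- R / rs
  Tn <- Tm / ts
  # project onto the smooth-spectrum basis
  bc <- seq(min(grid), max(grid), by = basis_spacing_nm)
  S <- vapply(bc, function(c0) {
    exp(-((grid - c0)^2) / (2 * basis_sigma_nm^2))
  }, numeric(length(grid)))
  RB <- Rn %*% S
  TB <- Tn %*% S
  G <- RB %*% t(RB)
  lam <- ridge * mean(diag(G))
  A <- G + diag(lam, nb)
  Ct <- tryCatch(
    t(solve(A, RB %*% t(TB))),  # C^T = TB RB' (RB RB' + lam I)^-1
    error = function(e) {
      stop("singular band-overlap Gram matrix; increase ridge > 0 (",
           conditionMessage(e), ")", call. = FALSE)
    })
  C <- t(Ct)
  if (normalize) {
    cs <- colSums(C)
    if (any(abs(cs) < 1e-12)) {
      stop("degenerate correction matrix: zero column sum", call. = FALSE)
    }
    C <- sweep(C, 2L, cs, "/")
  }
  structure(list(matrix = C, ridge = ridge, target_bandset = target,
                 illumination_kind = if (is.null(illumination)) "flat" else
                   illumination_kind(illumination) %||% "custom"),
            class = "correction_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf("<correction_matrix> %d x %d, ridge %g, illumination %s\n",
              nrow(x$matrix), ncol(x$matrix), x$ridge, x$illumination_kind))
  invisible(x)
}

#' Apply the spectral correction to a cube
#'
#' Per pixel, the band spectrum (row vector) is right-multiplied by the
#' correction matrix: `I_cor = I_res . C`. The corrected signal behaves as
#' if captured with nearly ideal filters; secondary-peak contamination is
#' removed in this step. Only performed for the snapshot-camera path.
#'
#' @param cube A [band_cube()].
#' @param C A `correction_matrix` (input dimension = cube band count).
#' @return The corrected cube with target band metadata.
#' @export
apply_spectral_correction <- function(cube, C) {
  stopifnot(inherits(C, "correction_matrix"))
  d <- dim(cube$data)
  if (nrow(C$matrix) != d[1]) {
    stop("cube band count does not match the correction matrix", call. = FALSE)
  }
  m <- cube_to_matrix(cube) %*% C$matrix
  out <- band_cube(matrix_to_cube_data(m, d[2], d[3]), C$target_bandset,
                   cube$unit,
                   provenance = c(cube$provenance, "spectral_correction"))
  attr(out, "exposure_ms") <- cube_exposure(cube)
  out
}
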