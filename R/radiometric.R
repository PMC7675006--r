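#' Temporal average of a dark-frame series
#'
#' Shielded-sensor frames are averaged per pixel to the dark reference
#' `I_dark`; their per-pixel temporal SD is the noise estimate entering the
#' SNR (signal amplitude over noise SD).
#'
#' @param frames List of equally shaped 2-D matrices (mosaic sensor) or
#'   band x h x w arrays (filter-wheel stacks).
#' @param exposure_ms Exposure the series was captured with.
#' @return A `dark_reference` with fields `mean_frame`, `noise_sd` (same
#'   shape), `exposure_ms`, `n_frames`; `sd_degenerate` is `TRUE` when only
#'   one frame was supplied (SD identically 0).
#' @export
average_dark <- function(frames, exposure_ms) {
  if (length(frames) < 1L) stop("need at least one dark frame", call. = FALSE)
  ref_dim <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), ref_dim)) {
      stop("all dark frames must share the same shape", call. = FALSE)
    }
  }
  n <- length(frames)
  stack <- array(unlist(frames), dim = c(ref_dim, n))
  nd <- length(ref_dim)
  mean_frame <- apply(stack, seq_len(nd), mean)
  noise_sd <- if (n == 1L) array(0, dim = ref_dim) else
    apply(stack, seq_len(nd), stats::sd)
  structure(list(mean_frame = mean_frame, noise_sd = noise_sd,
                 exposure_ms = exposure_ms, n_frames = n,
                 sd_degenerate = n == 1L),
            class = "dark_reference")
}

#' White reference acquisition
#'
#' @param frame The white-board image: a [mosaic_frame()], [frame_stack()],
#'   [band_cube()], matrix, or band x h x w array.
#' @param exposure_ms Exposure of the white acquisition (taken from `frame`
#'   when it carries one).
#' @param board_reflectance Reflectance of the calibration board, in (0, 1].
#' @return A `white_reference`.
#' @export
white_reference <- function(frame, exposure_ms = NULL,
                            board_reflectance = 0.95) {
  if (inherits(frame, "mosaic_frame")) {
    if (is.null(exposure_ms)) exposure_ms <- frame$exposure_ms
    frame <- frame$pixels
  } else if (inherits(frame, "frame_stack")) {
    if (is.null(exposure_ms)) exposure_ms <- frame$exposure_ms
    frame <- frame$frames
  } else if (inherits(frame, "band_cube")) {
    if (is.null(exposure_ms)) exposure_ms <- cube_exposure(frame)
    frame <- frame$data
  }
  if (is.null(exposure_ms)) {
    stop("white reference requires exposure metadata", call. = FALSE)
  }
  stopifnot(board_reflectance > 0, board_reflectance <= 1)
  structure(list(frame = frame, exposure_ms = exposure_ms,
                 board_reflectance = board_reflectance),
            class = "white_reference")
}

#' Dark-subtract a counts cube
#'
#' @param cube A [band_cube()] in counts.
#' @param dark A `dark_reference` whose mean frame matches the cube planes
#'   (2-D means are broadcast across bands).
#' @return The cube with the dark mean removed (values may go negative;
#'   they are kept, not clipped, to avoid biasing region means).
#' @export
subtract_dark <- function(cube, dark) {
  stopifnot(inherits(cube, "band_cube"), inherits(dark, "dark_reference"))
  d <- dim(cube$data)
  dm <- dark$mean_frame
  if (length(dim(dm)) == 3L) {
    stopifnot(identical(dim(dm), d))
    cube$data <- cube$data - dm
  } else {
    stopifnot(identical(dim(dm), d[2:3]))
    cube$data <- cube$data - rep(dm, each = d[1])
  }
  cube_note(cube, "dark_subtracted")
}

#' Estimate the flat-field gain from a uniform-target cube
#'
#' For each band, the reference intensity is the mean over a centered window
#' of half-width `center_window_px` pixels, and the gain at each pixel is
#' reference / measured. Estimated from a dark-subtracted render of a
#' spatially uniform target (in practice the white board), it removes
#' vignetting and aperture falloff.
#'
#' @param uniform_cube A dark-subtracted [band_cube()] of a uniform target.
#' @param center_window_px Half-width of the center window (the window is
#'   `(2*center_window_px + 1)^2` pixels).
#' @param min_signal_frac Pixels below this fraction of the band reference
#'   are masked (gain NA).
#' @return A `flat_field_gain` with a per-band gain array; fraction of
#'   masked pixels reported in `masked_frac` (warning above 5%).
#' @export
estimate_flat_field <- function(uniform_cube, center_window_px = 10L,
                                min_signal_frac = 1e-3) {
  d <- dim(uniform_cube$data)
  hw <- as.integer(center_window_px)
  if (2L * hw + 1L > d[2] || 2L * hw + 1L > d[3]) {
    stop("center window exceeds the image", call. = FALSE)
  }
  cy <- floor((d[2] + 1) / 2); cx <- floor((d[3] + 1) / 2)
  ys <- max(1L, cy - hw):min(d[2], cy + hw)
  xs <- max(1L, cx - hw):min(d[3], cx + hw)
  gain <- array(NA_real_, dim = d)
  n_masked <- 0L
  for (b in seq_len(d[1])) {
    plane <- uniform_cube$data[b, , ]
    i_ref <- mean(plane[ys, xs])
    bad <- !is.finite(plane) | plane <= min_signal_frac * i_ref
    g <- i_ref / plane
    g[bad] <- NA_real_
    n_masked <- n_masked + sum(bad)
    # renormalize so the center-window mean gain is exactly 1
    g <- g / mean(g[ys, xs], na.rm = TRUE)
    gain[b, , ] <- g
  }
  masked_frac <- n_masked / length(gain)
  if (masked_frac >= 0.05) {
    warning(sprintf("flat-field: %.1f%% of pixels masked", 100 * masked_frac))
  }
  structure(list(gain = gain, center_window_px = hw,
                 masked_frac = masked_frac),
            class = "flat_field_gain")
}

#' Apply a flat-field gain to a cube
#'
#' @param cube A [band_cube()].
#' @param gain A `flat_field_gain` of matching shape.
#' @return The element-wise corrected cube, provenance appended.
#' @export
apply_flat_field <- function(cube, gain) {
  stopifnot(inherits(gain, "flat_field_gain"))
  if (!identical(dim(cube$data), dim(gain$gain))) {
    stop("flat-field gain shape does not match the cube", call. = FALSE)
  }
  cube$data <- cube$data * gain$gain
  cube_note(cube, "flat_field")
}

#' Convert raw counts to reflectance (one-point white calibration)
#'
#' `I_res = (I_raw - I_dark|raw) / (I_white - I_dark|white) * (eps_white /
#' eps_raw)`: dark-corrected counts are normalized by the dark-corrected
#' white-board counts and rescaled by the exposure ratio. Pixels whose white
#' denominator is not positive are masked `NA`. By default the literal
#' one-point formula is used; `apply_board_reflectance = TRUE` additionally
#' multiplies by the board reflectance (0.95) so that a perfect system maps
#' a 95% board to reflectance 0.95 instead of 1.
#'
#' @param raw A [band_cube()] in counts carrying an `exposure_ms` attribute
#'   (or pass `exposure_ms`).
#' @param dark `dark_reference` for the raw exposure, or `NULL` if `raw` is
#'   already dark-subtracted.
#' @param white A [white_reference()].
#' @param white_dark `dark_reference` for the white exposure, or `NULL` if
#'   the white frame is already dark-subtracted.
#' @param exposure_ms Raw exposure override (ms).
#' @param apply_board_reflectance Correct for the board's true reflectance?
#' @return A [band_cube()] in reflectance units. Negative values (noise
#'   below dark) are kept and counted in attribute `n_negative`.
#' @export
to_reflectance <- function(raw, dark, white, white_dark,
                           exposure_ms = cube_exposure(raw),
                           apply_board_reflectance = FALSE) {
  stopifnot(inherits(raw, "band_cube"), inherits(white, "white_reference"))
  if (raw$unit != "counts") stop("raw cube must be in counts", call. = FALSE)
  if (is.null(exposure_ms)) {
    stop("raw cube has no exposure metadata; pass exposure_ms", call. = FALSE)
  }
  d <- dim(raw$data)
  num <- raw$data
  if (!is.null(dark)) {
    num <- subtract_dark(raw, dark)$data
  } else if (!"dark_subtracted" %in% raw$provenance) {
    stop("dark is NULL but the raw cube is not marked dark_subtracted",
         call. = FALSE)
  }
  wf <- white$frame
  if (!is.null(white_dark)) {
    wdm <- white_dark$mean_frame
    if (length(dim(wf)) == 2L && length(dim(wdm)) == 2L) {
      wf <- wf - wdm
    } else if (length(dim(wf)) == 3L) {
      wf <- if (length(dim(wdm)) == 3L) wf - wdm else
        wf - rep(wdm, each = dim(wf)[1])
    } else stop("white/dark shape mismatch", call. = FALSE)
  }
  den <- if (length(dim(wf)) == 3L) {
    stopifnot(identical(dim(wf), d))
    wf
  } else {
    stopifnot(identical(dim(wf), d[2:3]))
    array(rep(wf, each = d[1]), dim = d)
  }
  den[den <= 0] <- NA_real_
  res <- num / den * (white$exposure_ms / exposure_ms)
  if (apply_board_reflectance) res <- res * white$board_reflectance
  out <- band_cube(res, raw$bandset, "reflectance",
                   provenance = c(raw$provenance, "reflectance"))
  attr(out, "n_negative") <- sum(res < 0, na.rm = TRUE)
  attr(out, "n_masked") <- sum(is.na(res))
  out
}

#' Per-band signal-to-noise ratio
#'
#' `SNR = A_signal / sigma_noise` with the noise SD taken from the
#' dark-frame stack: per band, the spatial median of the per-pixel temporal
#' SD map.
#'
#' @param signal_amplitude Per-band signal amplitudes (counts).
#' @param dark A `dark_reference`.
#' @return Numeric vector of per-band SNR values.
#' @export
compute_snr <- function(signal_amplitude, dark) {
  stopifnot(inherits(dark, "dark_reference"))
  sd_map <- dark$noise_sd
  sigma <- if (length(dim(sd_map)) == 3L) {
    apply(sd_map, 1L, stats::median)
  } else {
    rep(stats::median(sd_map), length(signal_amplitude))
  }
  if (length(sigma) == 1L) sigma <- rep(sigma, length(signal_amplitude))
  if (any(sigma <= 0)) {
    stop("sigma_noise is zero: SNR undefined (degenerate dark series)",
         call. = FALSE)
  }
  as.numeric(signal_amplitude) / sigma
}
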