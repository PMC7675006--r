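#' Scene model
#'
#' A labelled spatial layout plus one reflectance spectrum per label: the
#' stand-in for whatever is in front of the camera (reference chart, situs).
#'
#' @param tile_map Integer or character matrix of per-pixel labels.
#' @param label_spectra Named list of [spectral_curve()] reflectances, one per
#'   label occurring in `tile_map`; values must lie in \[0, 1\].
#' @return An object of class `scene_model`.
#' @export
scene_model <- function(tile_map, label_spectra) {
  tile_map <- as.matrix(tile_map)
  labs <- unique(as.vector(tile_map))
  missing <- setdiff(as.character(labs), names(label_spectra))
  if (length(missing)) {
    stop("labels without a spectrum: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(label_spectra)) {
    v <- label_spectra[[nm]]$value
    if (any(v > 1 + 1e-9)) stop("scene reflectance must be <= 1", call. = FALSE)
  }
  structure(list(tile_map = tile_map, label_spectra = label_spectra),
            class = "scene_model")
}

#' Lay out a reference chart as a scene
#'
#' Places the 24 tiles on a 4 x 6 grid of square patches.
#'
#' @param chart A [reference_chart()].
#' @param tile_px Patch edge length in pixels; for mosaic cameras use a
#'   multiple of the pattern so each demosaiced pixel lies inside one tile.
#' @return A [scene_model()] whose labels are the tile names.
#' @export
make_chart_scene <- function(chart, tile_px = 16L) {
  tile_px <- as.integer(tile_px)
  lay <- matrix(chart$tile_names, nrow = 4L, ncol = 6L, byrow = TRUE)
  tile_map <- lay[rep(seq_len(4L), each = tile_px),
                  rep(seq_len(6L), each = tile_px)]
  spectra <- lapply(chart$tile_names, function(nm) chart_tile_curve(chart, nm))
  names(spectra) <- chart$tile_names
  scene_model(tile_map, spectra)
}

#' Uniform single-reflectance scene
#' @param height,width Scene size in pixels.
#' @param reflectance Flat reflectance level in \[0, 1\].
#' @return A [scene_model()] with one label `"uniform"`.
#' @export
make_uniform_scene <- function(height, width, reflectance = 0.95) {
  scene_model(matrix("uniform", height, width),
              list(uniform = spectral_curve(range(working_grid()),
                                            rep(reflectance, 2L))))
}

#' Per-tile masks of a chart scene at cube resolution
#'
#' @param scene A chart [scene_model()].
#' @param pattern Mosaic period (1 for filter-wheel): masks are produced at
#'   the demosaiced resolution `dim(scene)/pattern`.
#' @return Named list of logical matrices, one per label.
#' @export
scene_tile_masks <- function(scene, pattern = 1L) {
  tm <- scene$tile_map
  sub <- tm[seq(1L, nrow(tm), by = pattern), seq(1L, ncol(tm), by = pattern),
            drop = FALSE]
  labs <- names(scene$label_spectra)
  out <- lapply(labs, function(l) sub == l)
  names(out) <- labs
  out
}

#' Acquisition parameters for the forward model
#'
#' @param exposure_ms Exposure time in ms (the epsilon of the reflectance
#'   conversion), positive.
#' @param full_well_counts Saturation ceiling in counts (12-bit by default).
#' @param dark_offset_counts Mean dark-current level in counts.
#' @param read_noise_sd_counts SD of the Gaussian read noise, >= 0.
#' @param shot_noise Apply Poisson shot noise to the signal counts?
#' @param vignetting_strength Corner falloff in \[0, 1): the lens profile is
#'   `1 - strength * r^4` with `r` the center distance normalized to 1 at the
#'   corners.
#' @param gain_counts Sensor gain in counts per (ms x unit radiance x nm),
#'   chosen so the brightest band at the packaged optimal exposures sits
#'   near, but below, the full well.
#' @param seed RNG seed for the noise draws (`NULL` = use the current RNG
#'   state).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(exposure_ms,
                               full_well_counts = 4095,
                               dark_offset_counts = 100,
                               read_noise_sd_counts = 2,
                               shot_noise = TRUE,
                               vignetting_strength = 0.2,
                               gain_counts = 3,
                               seed = NULL) {
  stopifnot(exposure_ms > 0, read_noise_sd_counts >= 0,
            dark_offset_counts < full_well_counts,
            vignetting_strength >= 0, vignetting_strength < 1)
  structure(list(exposure_ms = exposure_ms,
                 full_well_counts = full_well_counts,
                 dark_offset_counts = dark_offset_counts,
                 read_noise_sd_counts = read_noise_sd_counts,
                 shot_noise = isTRUE(shot_noise),
                 vignetting_strength = vignetting_strength,
                 gain_counts = gain_counts,
                 seed = seed),
            class = "acquisition_params")
}

#' Noiseless variant of acquisition parameters
#' @param acq An [acquisition_params()].
#' @return The same parameters with shot noise off and zero read noise.
#' @export
noiseless <- function(acq) {
  acq$shot_noise <- FALSE
  acq$read_noise_sd_counts <- 0
  acq
}

# Radial quartic vignetting profile, 1 at center, 1 - strength at corners.
vignette_profile <- function(height, width, strength) {
  if (strength <= 0) return(matrix(1, height, width))
  cy <- (height + 1) / 2
  cx <- (width + 1) / 2
  rmax2 <- (1 - cy)^2 + (1 - cx)^2
  y2 <- ((seq_len(height) - cy)^2)
  x2 <- ((seq_len(width) - cx)^2)
  r2 <- outer(y2, x2, "+") / rmax2
  1 - strength * r2^2
}

# Grid step of a uniformly spaced wavelength grid.
grid_step <- function(grid) {
  d <- diff(grid)
  if (max(abs(d - d[1])) > 1e-9) stop("grid must be uniform", call. = FALSE)
  d[1]
}

# Per-label, per-band noiseless band integrals:
#   integral[l, b] = sum_lambda illum * reflectance_l * response_b * dlambda
band_integrals <- function(scene, illumination, grid, responses) {
  ill <- curve_at(illumination, grid)
  labs <- names(scene$label_spectra)
  refl <- vapply(labs, function(l) curve_at(scene$label_spectra[[l]], grid),
                 numeric(length(grid)))
  step <- grid_step(grid)
  out <- (responses %*% (refl * ill)) * step   # nb x nlabels
  t(out)                                       # nlabels x nb
}

# Shared noise + saturation model applied to a noiseless signal image.
apply_sensor_noise <- function(signal, acq) {
  if (acq$shot_noise) {
    signal[] <- stats::rpois(length(signal), lambda = pmax(signal, 0))
  }
  counts <- signal + acq$dark_offset_counts
  if (acq$read_noise_sd_counts > 0) {
    counts <- counts + stats::rnorm(length(counts),
                                    sd = acq$read_noise_sd_counts)
  }
  matrix(pmin(pmax(counts, 0), acq$full_well_counts),
         nrow = nrow(signal), ncol = ncol(signal))
}

with_acq_seed <- function(acq, expr) {
  if (is.null(acq$seed)) expr else withr::with_seed(as.integer(acq$seed), expr)
}

#' Raw mosaic frame
#'
#' @param pixels 2-D count image, dimensions multiples of the pattern.
#' @param bandset A mosaic `band_set` (pattern > 1).
#' @param exposure_ms Exposure used for the frame.
#' @return An object of class `mosaic_frame`.
#' @export
mosaic_frame <- function(pixels, bandset, exposure_ms) {
  p <- band_pattern(bandset)
  if (p <= 1L) stop("mosaic_frame requires a mosaic bandset (pattern > 1)",
                    call. = FALSE)
  if (nrow(pixels) %% p != 0L || ncol(pixels) %% p != 0L) {
    stop("frame dimensions must be multiples of the mosaic pattern",
         call. = FALSE)
  }
  structure(list(pixels = pixels, bandset = bandset,
                 exposure_ms = exposure_ms), class = "mosaic_frame")
}

#' Filter-wheel frame stack
#'
#' @param frames Band x height x width array of count images, one frame per
#'   wheel band, shared exposure.
#' @param bandset The filter-wheel `band_set`.
#' @param exposure_ms Per-band exposure in ms.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, bandset, exposure_ms) {
  stopifnot(length(dim(frames)) == 3L)
  if (dim(frames)[1] != n_bands(bandset)) {
    stop("frame count must equal band count", call. = FALSE)
  }
  structure(list(frames = frames, bandset = bandset,
                 exposure_ms = exposure_ms), class = "frame_stack")
}

# Map each mosaic pixel to its (sorted) band index.
mosaic_band_map <- function(height, width, bandset) {
  p <- band_pattern(bandset)
  pos <- outer((seq_len(height) - 1L) %% p * p, (seq_len(width) - 1L) %% p, "+")
  # sensor position -> sorted band index lookup (positions beyond the band
  # count cannot occur because pattern^2 == band count for packaged setups)
  lut <- integer(p * p)
  lut[bandset$sensor_index + 1L] <- seq_len(n_bands(bandset))
  matrix(lut[pos + 1L], height, width)
}

#' Render a raw snapshot mosaic frame
#'
#' Physical image formation for a mosaic camera: each pixel integrates
#' illumination x scene reflectance x its band's response over wavelength,
#' scaled by exposure and gain, attenuated by the radial vignetting profile,
#' then dark offset, optional Poisson shot noise, Gaussian read noise and
#' saturation clipping are applied.
#'
#' @param scene A [scene_model()]; dimensions must be multiples of the
#'   mosaic pattern.
#' @param illumination An illumination [spectral_curve()].
#' @param responses A [sensor_response_set()] for a mosaic band set.
#' @param acq An [acquisition_params()].
#' @return A [mosaic_frame()].
#' @export
render_mosaic_frame <- function(scene, illumination, responses, acq) {
  bandset <- responses$bandset
  p <- band_pattern(bandset)
  h <- nrow(scene$tile_map); w <- ncol(scene$tile_map)
  if (h %% p != 0L || w %% p != 0L) {
    stop("scene dimensions must be multiples of the mosaic pattern",
         call. = FALSE)
  }
  ints <- band_integrals(scene, illumination, responses$grid,
                         responses$responses)
  labs <- names(scene$label_spectra)
  label_id <- matrix(match(as.vector(scene$tile_map), labs), h, w)
  band_id <- mosaic_band_map(h, w, bandset)
  signal <- matrix(ints[cbind(as.vector(label_id), as.vector(band_id))], h, w)
  signal <- signal * acq$exposure_ms * acq$gain_counts *
    vignette_profile(h, w, acq$vignetting_strength)
  pixels <- with_acq_seed(acq, apply_sensor_noise(signal, acq))
  mosaic_frame(pixels, bandset, acq$exposure_ms)
}

#' Render a filter-wheel frame stack
#'
#' Sequential monochromatic illumination: each frame is lit by a Gaussian
#' band (center/FWHM from the wheel table) carved out of the broadband source
#' envelope, recorded by a panchromatic sensor with flat quantum efficiency.
#' Noise and vignetting as in [render_mosaic_frame()].
#'
#' @param scene A [scene_model()].
#' @param bandset The `filter_wheel` band set.
#' @param acq An [acquisition_params()].
#' @param envelope Broadband source spectrum (default xenon).
#' @return A [frame_stack()].
#' @export
render_filterwheel_stack <- function(scene, bandset, acq,
                                     envelope = make_illumination("xenon")) {
  if (band_pattern(bandset) != 1L) {
    stop("render_filterwheel_stack requires the filter_wheel bandset",
         call. = FALSE)
  }
  grid <- working_grid()
  h <- nrow(scene$tile_map); w <- ncol(scene$tile_map)
  env_v <- curve_at(envelope, grid)
  # band illumination spectra play the role of per-frame responses here
  band_ill <- t(vapply(seq_len(n_bands(bandset)), function(b) {
    gaussian_band_response(bandset$center_nm[b], bandset$fwhm_nm[b],
                           grid)$value * env_v
  }, numeric(length(grid))))
  ints <- band_integrals(scene, make_illumination("flat", grid), grid,
                         band_ill)
  labs <- names(scene$label_spectra)
  label_id <- match(as.vector(scene$tile_map), labs)
  vig <- vignette_profile(h, w, acq$vignetting_strength)
  frames <- array(0, dim = c(n_bands(bandset), h, w))
  with_acq_seed(acq, {
    for (b in seq_len(n_bands(bandset))) {
      signal <- matrix(ints[label_id, b], h, w) *
        acq$exposure_ms * acq$gain_counts * vig
      frames[b, , ] <- apply_sensor_noise(signal, acq)
    }
  })
  frame_stack(frames, bandset, acq$exposure_ms)
}

#' Render dark-frame series and white-reference acquisition
#'
#' Dark frames are signal-free renders (illumination off: dark offset plus
#' read noise only). The white frame images a uniform 95%-reflectance
#' calibration board with its own exposure, reported in the result's
#' metadata.
#'
#' @param acq An [acquisition_params()] (its `exposure_ms` applies to the
#'   dark series).
#' @param illumination Illumination spectrum for the white render.
#' @param responses_or_bandset A [sensor_response_set()] (mosaic path) or the
#'   filter-wheel `band_set`.
#' @param n_dark Number of dark frames, >= 1.
#' @param n_white Number of white frames averaged into the white reference
#'   (the board is uniform and static, so temporal averaging is standard
#'   practice; it keeps the denominator of the reflectance conversion
#'   well-conditioned at low SNR).
#' @param shape `c(height, width)` of the sensor area to simulate.
#' @param white_exposure_ms Exposure for the white frame (default: same as
#'   `acq`).
#' @param board_reflectance Reflectance of the calibration board.
#' @param envelope Source envelope for the filter-wheel path.
#' @return A list with `dark_frames` (list of 2-D matrices for the mosaic
#'   path, or a list of band x h x w arrays for the filter-wheel path),
#'   `white` (a [mosaic_frame()] or [frame_stack()]), and
#'   `white_exposure_ms`.
#' @export
render_reference_frames <- function(acq, illumination, responses_or_bandset,
                                    n_dark = 50L, n_white = 20L,
                                    shape = c(64L, 64L),
                                    white_exposure_ms = acq$exposure_ms,
                                    board_reflectance = 0.95,
                                    envelope = make_illumination("xenon")) {
  stopifnot(n_dark >= 1L, n_white >= 1L)
  h <- shape[1]; w <- shape[2]
  mosaic_path <- inherits(responses_or_bandset, "sensor_response_set")
  bandset <- if (mosaic_path) responses_or_bandset$bandset else responses_or_bandset
  board <- make_uniform_scene(h, w, board_reflectance)
  white_acq <- acq
  white_acq$exposure_ms <- white_exposure_ms
  white_acq$seed <- NULL
  dark_acq <- acq
  dark_acq$seed <- NULL
  out <- with_acq_seed(acq, {
    darks <- lapply(seq_len(n_dark), function(i) {
      if (mosaic_path) {
        apply_sensor_noise(matrix(0, h, w), dark_acq)
      } else {
        frames <- array(0, dim = c(n_bands(bandset), h, w))
        for (b in seq_len(n_bands(bandset))) {
          frames[b, , ] <- apply_sensor_noise(matrix(0, h, w), dark_acq)
        }
        frames
      }
    })
    white <- NULL
    for (i in seq_len(n_white)) {
      w <- if (mosaic_path) {
        render_mosaic_frame(board, illumination, responses_or_bandset,
                            white_acq)
      } else {
        render_filterwheel_stack(board, bandset, white_acq,
                                 envelope = envelope)
      }
      if (is.null(white)) {
        white <- w
      } else if (mosaic_path) {
        white$pixels <- white$pixels + w$pixels
      } else {
        white$frames <- white$frames + w$frames
      }
    }
    if (mosaic_path) white$pixels <- white$pixels / n_white else
      white$frames <- white$frames / n_white
    list(dark_frames = darks, white = white)
  })
  out$white_exposure_ms <- white_exposure_ms
  out
}
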