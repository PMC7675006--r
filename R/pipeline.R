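#' Simulate a complete chart acquisition
#'
#' Forward-models everything one calibration run needs: the band table and
#' sensor responses of the chosen setup (default secondary peaks for the NIR
#' mosaic camera), the illumination spectrum, a chart scene, the raw
#' acquisition, a dark-frame series and a white-reference frame, plus the
#' per-tile masks and ground truth.
#'
#' @param setup_name `"filter_wheel"`, `"cam4x4"` or `"cam5x5"`.
#' @param illumination_kind `"xenon"`, `"led"` or `"flat"`.
#' @param chart A [reference_chart()] (default: synthetic chart from `seed`).
#' @param seed Integer seed driving chart generation and all noise.
#' @param noise Simulate shot and read noise? (`FALSE` = exact forward
#'   model.)
#' @param tile_px Chart patch edge in pixels (default `8 * pattern`,
#'   so each tile spans an 8 x 8 region at cube resolution).
#' @param n_dark Number of dark frames.
#' @param exposure_ms Exposure (default: the packaged optimal exposure).
#' @param responses Override the sensor responses (a [sensor_response_set()]
#'   on the setup's band set); default: synthetic responses with the
#'   packaged peak heights and default secondary peaks.
#' @param ... Further arguments to [acquisition_params()].
#' @return A list of class `hsi_acquisition` with fields `setup_name`,
#'   `illumination_kind`, `bandset`, `responses`, `illumination`, `scene`,
#'   `chart`, `masks`, `acq`, `raw`, `dark_frames`, `white`,
#'   `white_exposure_ms`.
#' @export
simulate_acquisition <- function(setup_name, illumination_kind = "xenon",
                                 chart = NULL, seed = 1L, noise = TRUE,
                                 tile_px = NULL, n_dark = 20L,
                                 exposure_ms = NULL, responses = NULL, ...) {
  bandset <- load_band_table(setup_name)
  pattern <- band_pattern(bandset)
  if (is.null(chart)) chart <- make_reference_chart(seed)
  if (is.null(tile_px)) tile_px <- 8L * pattern
  if (is.null(exposure_ms)) {
    exposure_ms <- if (illumination_kind == "flat") 40 else
      default_exposure_ms(setup_name, illumination_kind)
  }
  illumination <- make_illumination(illumination_kind)
  if (is.null(responses) && pattern > 1L) {
    responses <- make_sensor_responses(bandset, secondary_peaks = "default")
  }
  scene <- make_chart_scene(chart, tile_px)
  acq <- acquisition_params(exposure_ms = exposure_ms,
                            seed = as.integer(seed) + 1000L, ...)
  if (!noise) acq <- noiseless(acq)
  raw <- if (pattern > 1L) {
    render_mosaic_frame(scene, illumination, responses, acq)
  } else {
    render_filterwheel_stack(scene, bandset, acq,
                             envelope = if (illumination_kind == "flat")
                               make_illumination("flat") else illumination)
  }
  ref_acq <- acq
  ref_acq$seed <- as.integer(seed) + 2000L
  refs <- render_reference_frames(ref_acq, illumination,
                                  if (pattern > 1L) responses else bandset,
                                  n_dark = n_dark,
                                  shape = dim(scene$tile_map),
                                  envelope = if (illumination_kind == "flat")
                                    make_illumination("flat") else illumination)
  structure(list(setup_name = setup_name,
                 illumination_kind = illumination_kind, bandset = bandset,
                 responses = responses, illumination = illumination,
                 scene = scene, chart = chart,
                 masks = scene_tile_masks(scene, pattern), acq = acq,
                 raw = raw, dark_frames = refs$dark_frames,
                 white = refs$white,
                 white_exposure_ms = refs$white_exposure_ms),
            class = "hsi_acquisition")
}

#' Run the calibration chain on an acquisition
#'
#' The full chain: dark averaging, (demosaic for the snapshot path),
#' flat-field estimation from the dark-subtracted white frame and
#' application to raw and white, one-point conversion to reflectance,
#' spectral crosstalk correction (snapshot path only), intensity-correction
#' fit against the chart (wavelengths above the cutoff excluded) and
#' application, and validation against the chart.
#'
#' @param acquisition An `hsi_acquisition` (from [simulate_acquisition()] or
#'   assembled from file inputs).
#' @param lambda_max_nm Fit cutoff for the intensity correction.
#' @param ridge Regularization for the correction matrix.
#' @param alpha `"fit"` or a fixed positive scalar.
#' @param board_reflectance_correction Divide out the white board's true
#'   reflectance in the conversion step.
#' @param center_window_px Flat-field center window half-width (defaults to
#'   10, shrunk to fit small simulated sensors).
#' @param spectral_correction Apply the crosstalk correction matrix on the
#'   snapshot path? (`FALSE` leaves the raw band mixing in place, for
#'   ablation studies.)
#' @return A list of class `hsi_calibration`: `cube` (I_final), `reflectance`
#'   (I_res before intensity correction), `alpha` (`scale_correction`),
#'   `report` (`validation_report`), `correction` (the `correction_matrix`
#'   or `NULL`), `dark`, `snr` (per-band SNR of the white signal),
#'   `provenance`.
#' @export
calibrate_acquisition <- function(acquisition, lambda_max_nm = 850,
                                  ridge = 1e-4, alpha = "fit",
                                  board_reflectance_correction = FALSE,
                                  center_window_px = NULL,
                                  spectral_correction = TRUE) {
  a <- acquisition
  pattern <- band_pattern(a$bandset)
  mosaic <- pattern > 1L
  dark <- average_dark(a$dark_frames, a$acq$exposure_ms)
  if (mosaic) {
    raw_cube <- demosaic(a$raw)
    white_cube <- demosaic(a$white)
    dark_cube <- demosaic_dark(dark, a$bandset)
  } else {
    raw_cube <- stack_to_cube(a$raw)
    white_cube <- stack_to_cube(a$white)
    dark_cube <- dark
  }
  raw_sub <- subtract_dark(raw_cube, dark_cube)
  white_sub <- subtract_dark(white_cube, dark_cube)
  if (is.null(center_window_px)) {
    center_window_px <- min(10L, (min(dim(white_sub$data)[2:3]) - 1L) %/% 2L)
  }
  ff <- estimate_flat_field(white_sub, center_window_px = center_window_px)
  raw_ff <- apply_flat_field(raw_sub, ff)
  white_ff <- apply_flat_field(white_sub, ff)
  white_ref <- white_reference(white_ff$data,
                               exposure_ms = a$white_exposure_ms)
  i_res <- to_reflectance(raw_ff, NULL, white_ref, NULL,
                          exposure_ms = a$acq$exposure_ms,
                          apply_board_reflectance =
                            board_reflectance_correction)
  correction <- NULL
  if (mosaic && spectral_correction) {
    correction <- build_correction_matrix(a$responses, a$bandset,
                                          ridge = ridge,
                                          illumination = a$illumination)
    i_res <- apply_spectral_correction(i_res, correction)
  }
  measured <- extract_tile_spectra(i_res, a$masks)
  sc <- if (identical(alpha, "fit")) {
    fit_alpha(measured, a$chart, lambda_max_nm = lambda_max_nm,
              setup_name = a$setup_name,
              illumination_kind = a$illumination_kind)
  } else {
    structure(list(alpha = as.numeric(alpha), lambda_max_nm = lambda_max_nm,
                   n_points = 0L, setup_name = a$setup_name,
                   illumination_kind = a$illumination_kind),
              class = "scale_correction")
  }
  final <- apply_alpha(i_res, sc)
  report <- validate_against_chart(final, a$chart, a$masks)
  white_amp <- apply(white_sub$data, 1L, stats::median)
  snr <- tryCatch(compute_snr(white_amp, dark_cube), error = function(e) NULL)
  structure(list(cube = final, reflectance = i_res, alpha = sc,
                 report = report, correction = correction, dark = dark_cube,
                 snr = snr, provenance = final$provenance),
            class = "hsi_calibration")
}

#' @export
print.hsi_calibration <- function(x, ...) {
  cat(sprintf("<hsi_calibration> %s/%s, alpha = %.4f\n",
              x$alpha$setup_name, x$alpha$illumination_kind, x$alpha$alpha))
  print(x$report)
  invisible(x)
}

#' Execute a configured calibration run
#'
#' Runs the calibration workflow for one setup end to end. With no raw input
#' path, the acquisition is simulated from the configuration's seed; with
#' `paths$raw`, `paths$dark` and `paths$white` set, cubes and references are
#' read from their text containers. Outputs (final reflectance cube,
#' validation report CSV, run summary JSON embedding the config) are written
#' under `paths$output` when given. Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return The `hsi_calibration` result, invisibly augmented with
#'   `output_files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$paths
  chart <- if (!is.null(p$chart)) read_spectra_csv(p$chart, as = "chart")
           else make_reference_chart(config$seed)
  bandset <- load_band_table(config$setup_name)
  if (is.null(p$raw)) {
    config_log(config, "simulating %s/%s acquisition (seed %d)",
               config$setup_name, config$illumination_kind, config$seed)
    acqn <- simulate_acquisition(config$setup_name, config$illumination_kind,
                                 chart = chart, seed = config$seed,
                                 noise = config$noise,
                                 tile_px = config$tile_px,
                                 n_dark = config$n_dark)
  } else {
    if (is.null(p$dark) || is.null(p$white) || is.null(p$masks)) {
      stop("file mode needs raw, dark, white and masks paths", call. = FALSE)
    }
    raw_cube <- read_cube(p$raw)
    white_cube <- read_cube(p$white)
    dark <- read_dark(p$dark)
    responses <- if (!is.null(p$responses)) {
      read_spectra_csv(p$responses, as = "responses", bandset = bandset)
    } else if (band_pattern(bandset) > 1L) {
      make_sensor_responses(bandset, secondary_peaks = "default")
    } else NULL
    acqn <- structure(list(
      setup_name = config$setup_name,
      illumination_kind = config$illumination_kind, bandset = bandset,
      responses = responses,
      illumination = make_illumination(config$illumination_kind),
      chart = chart, masks = read_masks(p$masks),
      acq = list(exposure_ms = cube_exposure(raw_cube)),
      raw = NULL, dark_frames = NULL, white = NULL,
      white_exposure_ms = cube_exposure(white_cube)),
      class = "hsi_acquisition")
    # file mode supplies cubes directly: bypass the render/demosaic stage
    return(run_pipeline_cubes(config, acqn, raw_cube, white_cube, dark))
  }
  result <- calibrate_acquisition(
    acqn, lambda_max_nm = config$lambda_max_nm, ridge = config$ridge,
    alpha = config$alpha,
    board_reflectance_correction = config$board_reflectance_correction)
  write_pipeline_outputs(config, result)
}

# Shared tail of the pipeline for pre-assembled cube inputs.
run_pipeline_cubes <- function(config, acqn, raw_cube, white_cube, dark) {
  mosaic <- band_pattern(acqn$bandset) > 1L
  if (mosaic && dim(raw_cube$data)[1] == 1L) {
    stop("file mode expects demosaiced cubes for snapshot setups",
         call. = FALSE)
  }
  raw_sub <- subtract_dark(raw_cube, dark)
  white_sub <- subtract_dark(white_cube, dark)
  hw <- min(10L, (min(dim(white_sub$data)[2:3]) - 1L) %/% 2L)
  ff <- estimate_flat_field(white_sub, center_window_px = hw)
  raw_ff <- apply_flat_field(raw_sub, ff)
  white_ff <- apply_flat_field(white_sub, ff)
  i_res <- to_reflectance(raw_ff, NULL,
                          white_reference(white_ff$data,
                                          acqn$white_exposure_ms), NULL,
                          exposure_ms = acqn$acq$exposure_ms,
                          apply_board_reflectance =
                            config$board_reflectance_correction)
  correction <- NULL
  if (mosaic) {
    correction <- build_correction_matrix(acqn$responses, acqn$bandset,
                                          ridge = config$ridge,
                                          illumination = acqn$illumination)
    i_res <- apply_spectral_correction(i_res, correction)
  }
  measured <- extract_tile_spectra(i_res, acqn$masks)
  sc <- if (identical(config$alpha, "fit")) {
    fit_alpha(measured, acqn$chart, lambda_max_nm = config$lambda_max_nm,
              setup_name = acqn$setup_name,
              illumination_kind = acqn$illumination_kind)
  } else {
    structure(list(alpha = as.numeric(config$alpha),
                   lambda_max_nm = config$lambda_max_nm, n_points = 0L,
                   setup_name = acqn$setup_name,
                   illumination_kind = acqn$illumination_kind),
              class = "scale_correction")
  }
  final <- apply_alpha(i_res, sc)
  report <- validate_against_chart(final, acqn$chart, acqn$masks)
  result <- structure(list(cube = final, reflectance = i_res, alpha = sc,
                           report = report, correction = correction,
                           dark = dark, snr = NULL,
                           provenance = final$provenance),
                      class = "hsi_calibration")
  write_pipeline_outputs(config, result)
}

write_pipeline_outputs <- function(config, result) {
  out <- config$paths$output
  files <- character()
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cube_stem <- file.path(out, "cube_final")
    write_cube(result$cube, cube_stem)
    rep_path <- file.path(out, "validation_report.csv")
    data.table::fwrite(result$report$points, rep_path)
    summary <- list(
      config = unclass(config),
      alpha = result$alpha$alpha,
      rmse = as.list(stats::setNames(result$report$rmse$rmse,
                                     result$report$rmse$region)),
      provenance = result$provenance)
    sum_path <- file.path(out, "run_summary.json")
    jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    files <- c(paste0(cube_stem, c(".json", ".csv")), rep_path, sum_path)
  }
  result$output_files <- files
  invisible(result)
}
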