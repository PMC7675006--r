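# Full-precision numeric matrix writer (fwrite trims to 15 significant
# digits; %.17g round-trips doubles exactly).
write_matrix_txt <- function(m, path) {
  ch <- matrix(formatC(m, format = "g", digits = 17), nrow(m), ncol(m))
  data.table::fwrite(data.table::as.data.table(ch), path,
                     col.names = FALSE, quote = FALSE)
}

#' Write / read a band cube as a text container
#'
#' Cubes are stored as a pair of plain-text files under a common stem: a
#' JSON sidecar (`<stem>.json`) carrying the band table, unit, exposure and
#' provenance, and a CSV (`<stem>.csv`) holding the band-stacked pixel
#' matrix (`bands * height` rows x `width` columns, full precision). The
#' round trip is lossless.
#'
#' @param cube A [band_cube()].
#' @param stem Path stem (no extension).
#' @return `write_cube` returns `stem` invisibly; `read_cube` returns the
#'   [band_cube()].
#' @export
write_cube <- function(cube, stem) {
  d <- dim(cube$data)
  bands <- as.data.frame(cube$bandset)
  meta <- list(container = "hsical-cube", version = 1L,
               setup = band_setup(cube$bandset),
               pattern = band_pattern(cube$bandset),
               unit = cube$unit, shape = d,
               exposure_ms = cube_exposure(cube),
               provenance = cube$provenance, bands = bands)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  stacked <- matrix(aperm(cube$data, c(2, 1, 3)), d[1] * d[2], d[3])
  write_matrix_txt(stacked, paste0(stem, ".csv"))
  invisible(stem)
}

#' @rdname write_cube
#' @export
read_cube <- function(stem) {
  side <- paste0(stem, ".json")
  body <- paste0(stem, ".csv")
  if (!file.exists(side)) stop("missing JSON sidecar: ", side, call. = FALSE)
  if (!file.exists(body)) stop("missing data file: ", body, call. = FALSE)
  meta <- jsonlite::fromJSON(side)
  if (!identical(meta$container, "hsical-cube")) {
    stop("not an hsical cube sidecar: ", side, call. = FALSE)
  }
  d <- as.integer(meta$shape)
  m <- as.matrix(data.table::fread(body, header = FALSE))
  if (nrow(m) != d[1] * d[2] || ncol(m) != d[3]) {
    stop(sprintf("cube data inconsistent with sidecar: %d x %d rows/cols for shape %s",
                 nrow(m), ncol(m), paste(d, collapse = "x")), call. = FALSE)
  }
  bs <- band_set(meta$setup, meta$bands$center_nm, meta$bands$fwhm_nm,
                 meta$bands$sensor_index, pattern = meta$pattern)
  if (!is.null(meta$bands$source)) bs$source <- meta$bands$source
  data <- aperm(array(m, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  cube <- band_cube(data, bs, meta$unit,
                    provenance = as.character(meta$provenance))
  if (!is.null(meta$exposure_ms)) {
    attr(cube, "exposure_ms") <- meta$exposure_ms
  }
  cube
}

#' Write / read a dark reference
#'
#' Mean and SD planes are stored as two stacked CSVs plus a JSON sidecar.
#'
#' @param dark A `dark_reference`.
#' @param stem Path stem.
#' @return `write_dark` returns `stem` invisibly; `read_dark` the
#'   `dark_reference`.
#' @export
write_dark <- function(dark, stem) {
  dm <- dark$mean_frame
  d <- dim(dm)
  meta <- list(container = "hsical-dark", version = 1L, shape = d,
               exposure_ms = dark$exposure_ms, n_frames = dark$n_frames)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  flatten <- function(x) {
    if (length(d) == 3L) matrix(aperm(x, c(2, 1, 3)), d[1] * d[2], d[3])
    else x
  }
  write_matrix_txt(flatten(dm), paste0(stem, "_mean.csv"))
  write_matrix_txt(flatten(dark$noise_sd), paste0(stem, "_sd.csv"))
  invisible(stem)
}

#' @rdname write_dark
#' @export
read_dark <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  if (!identical(meta$container, "hsical-dark")) {
    stop("not an hsical dark sidecar", call. = FALSE)
  }
  d <- as.integer(meta$shape)
  unflatten <- function(path) {
    m <- as.matrix(data.table::fread(path, header = FALSE))
    if (length(d) == 3L) aperm(array(m, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
    else matrix(m, d[1], d[2])
  }
  structure(list(mean_frame = unflatten(paste0(stem, "_mean.csv")),
                 noise_sd = unflatten(paste0(stem, "_sd.csv")),
                 exposure_ms = meta$exposure_ms, n_frames = meta$n_frames,
                 sd_degenerate = meta$n_frames == 1L),
            class = "dark_reference")
}

#' Write / read spectra tables as CSV
#'
#' CSV with header `wavelength_nm,<name>[,<name>_sd],...`; wavelengths must
#' be strictly increasing. Reference charts round-trip with their SD
#' columns; response sets are written without SD.
#'
#' @param x A [reference_chart()] or [sensor_response_set()].
#' @param path CSV file path.
#' @return `write_spectra_csv` returns `path` invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  if (inherits(x, "reference_chart")) {
    df <- data.frame(wavelength_nm = x$grid)
    for (nm in x$tile_names) {
      df[[nm]] <- x$reflectance[nm, ]
      df[[paste0(nm, "_sd")]] <- x$sd[nm, ]
    }
  } else if (inherits(x, "sensor_response_set")) {
    df <- data.frame(wavelength_nm = x$grid)
    for (b in seq_len(n_bands(x$bandset))) {
      df[[sprintf("band_%03d", b - 1L)]] <- x$responses[b, ]
    }
  } else stop("unsupported spectra object", call. = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param as `"chart"` to return a [reference_chart()], `"responses"` for a
#'   [sensor_response_set()] (requires `bandset`), `"table"` for a raw
#'   tibble.
#' @param bandset Band set for `as = "responses"`.
#' @export
read_spectra_csv <- function(path, as = c("chart", "responses", "table"),
                             bandset = NULL) {
  as <- match.arg(as)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (names(df)[1] != "wavelength_nm") {
    stop("spectra CSV must start with a wavelength_nm column", call. = FALSE)
  }
  wl <- df$wavelength_nm
  if (any(diff(wl) <= 0)) {
    stop("non-monotone wavelengths in spectra CSV", call. = FALSE)
  }
  cols <- setdiff(names(df), "wavelength_nm")
  sd_cols <- grep("_sd$", cols, value = TRUE)
  val_cols <- setdiff(cols, sd_cols)
  if (as == "table") return(tibble::as_tibble(df))
  if (as == "chart") {
    refl <- t(as.matrix(df[val_cols]))
    sd <- t(vapply(val_cols, function(nm) {
      sc <- paste0(nm, "_sd")
      if (sc %in% sd_cols) df[[sc]] else rep(0, length(wl))
    }, numeric(length(wl))))
    return(reference_chart(val_cols, wl, refl, sd))
  }
  if (is.null(bandset)) stop("bandset required for responses", call. = FALSE)
  sensor_response_set(bandset, wl, t(as.matrix(df[val_cols])))
}

#' Write / read chart tile masks
#'
#' Stored as an integer label matrix CSV plus a JSON legend mapping label
#' ids to tile names.
#'
#' @param masks Named list of logical matrices.
#' @param stem Path stem.
#' @return `write_masks` returns `stem` invisibly; `read_masks` the list.
#' @export
write_masks <- function(masks, stem) {
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  jsonlite::write_json(list(container = "hsical-masks",
                            tiles = names(masks)),
                       paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE)
  data.table::fwrite(data.table::as.data.table(lab), paste0(stem, ".csv"),
                     col.names = FALSE)
  invisible(stem)
}

#' @rdname write_masks
#' @export
read_masks <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  lab <- as.matrix(data.table::fread(paste0(stem, ".csv"), header = FALSE))
  out <- lapply(seq_along(meta$tiles), function(i) {
    m <- lab == i
    dimnames(m) <- NULL
    m
  })
  names(out) <- meta$tiles
  out
}

#' Run configuration
#'
#' A single JSON-serializable document describing one calibration run:
#' setup, illumination, file paths, calibration options and seed. Unknown
#' keys are rejected when read back.
#'
#' @param setup_name `"filter_wheel"`, `"cam4x4"` or `"cam5x5"`.
#' @param illumination_kind `"xenon"`, `"led"` or `"flat"`.
#' @param paths Named list of optional paths: `raw`, `dark`, `white`,
#'   `white_dark`, `responses`, `chart`, `masks`, `output`. When `raw` is
#'   absent the pipeline simulates the acquisition itself.
#' @param lambda_max_nm Intensity-correction fit cutoff.
#' @param ridge Spectral-correction regularization.
#' @param alpha `"fit"` or a fixed positive scalar.
#' @param board_reflectance_correction Divide out the white board's true
#'   reflectance in the conversion step?
#' @param max_shift Registration search radius.
#' @param noise Simulate with noise (simulation mode only)?
#' @param n_dark Dark frames to simulate.
#' @param tile_px Chart patch size in pixels (simulation mode).
#' @param seed Integer seed for all randomness in the run.
#' @param log_level `"quiet"` or `"info"`.
#' @return A `run_config`.
#' @export
run_config <- function(setup_name = "cam4x4", illumination_kind = "xenon",
                       paths = list(), lambda_max_nm = 850, ridge = 1e-4,
                       alpha = "fit", board_reflectance_correction = FALSE,
                       max_shift = 8L, noise = TRUE, n_dark = 20L,
                       tile_px = NULL, seed = 1L, log_level = "quiet") {
  stopifnot(setup_name %in% c("filter_wheel", "cam4x4", "cam5x5"),
            illumination_kind %in% c("xenon", "led", "flat"))
  known_paths <- c("raw", "dark", "white", "white_dark", "responses",
                   "chart", "masks", "output")
  bad <- setdiff(names(paths), known_paths)
  if (length(bad)) stop("unknown path keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(setup_name = setup_name,
                 illumination_kind = illumination_kind, paths = paths,
                 lambda_max_nm = lambda_max_nm, ridge = ridge, alpha = alpha,
                 board_reflectance_correction =
                   isTRUE(board_reflectance_correction),
                 max_shift = as.integer(max_shift), noise = isTRUE(noise),
                 n_dark = as.integer(n_dark), tile_px = tile_px,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` (for `write_run_config`).
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x$paths <- as.list(x$paths)
  do.call(run_config, x)
}

config_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf(paste0("[hsical] ", fmt), ...))
  }
  invisible(NULL)
}
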