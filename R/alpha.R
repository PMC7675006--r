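#' Fit the intensity-correction scaling factor
#'
#' Systematic scale shifts between reconstructed and reference reflectance
#' are absorbed by a single scalar per setup, `I_final = alpha * I_res`.
#' The scalar is fitted by least squares through the origin pooled over all
#' tiles: `alpha = sum(m * r) / sum(m^2)` with `m` the measured and `r` the
#' reference reflectance. Because the NIR suffers from very low SNR and
#' large reference SD, samples above `lambda_max_nm` (850 nm by default) are
#' excluded from the fit.
#'
#' @param measured Measured tile spectra: either a tibble with columns
#'   `tile`, `wavelength_nm`, `value` (as from [extract_tile_spectra()]) or a
#'   named list of [spectral_curve()]s keyed by tile name.
#' @param chart A [reference_chart()] supplying the reference reflectance.
#' @param lambda_max_nm Fit cutoff in nm; samples above it are ignored.
#' @param setup_name,illumination_kind Optional labels stored on the result.
#' @return A `scale_correction` with fields `alpha`, `lambda_max_nm`,
#'   `n_points`, `setup_name`, `illumination_kind`.
#' @examples
#' ch <- make_reference_chart(seed = 1)
#' m <- lapply(ch$tile_names, function(t) {
#'   spectral_curve(ch$grid, ch$reflectance[t, ] / 2.01)
#' })
#' names(m) <- ch$tile_names
#' fit_alpha(m, ch)$alpha  # 2.01
#' @export
fit_alpha <- function(measured, chart, lambda_max_nm = 850,
                      setup_name = NA_character_,
                      illumination_kind = NA_character_) {
  tbl <- as_measured_table(measured)
  tiles <- intersect(unique(tbl$tile), chart$tile_names)
  if (!length(tiles)) stop("no measured tile matches the chart", call. = FALSE)
  num <- 0; den <- 0; n_used <- 0L
  for (t in tiles) {
    sub <- tbl[tbl$tile == t, ]
    keep <- is.finite(sub$value) & sub$wavelength_nm <= lambda_max_nm &
      sub$wavelength_nm >= min(chart$grid) & sub$wavelength_nm <= max(chart$grid)
    if (!any(keep)) next
    r <- curve_at(chart_tile_curve(chart, t), sub$wavelength_nm[keep])
    m <- sub$value[keep]
    num <- num + sum(m * r)
    den <- den + sum(m * m)
    n_used <- n_used + sum(keep)
  }
  if (n_used < 2L) stop("not enough usable points below the cutoff",
                        call. = FALSE)
  alpha <- num / den
  if (!is.finite(alpha) || alpha <= 0) {
    stop("degenerate fit: alpha must be positive", call. = FALSE)
  }
  structure(list(alpha = alpha, lambda_max_nm = lambda_max_nm,
                 n_points = n_used, setup_name = setup_name,
                 illumination_kind = illumination_kind),
            class = "scale_correction")
}

as_measured_table <- function(measured) {
  if (is.data.frame(measured)) {
    stopifnot(all(c("tile", "wavelength_nm", "value") %in% names(measured)))
    return(measured)
  }
  if (is.list(measured) && !is.null(names(measured))) {
    rows <- lapply(names(measured), function(nm) {
      sc <- measured[[nm]]
      tibble::tibble(tile = nm, wavelength_nm = sc$wavelength_nm,
                     value = sc$value)
    })
    return(do.call(rbind, rows))
  }
  stop("measured must be a tile/wavelength/value table or a named list of curves",
       call. = FALSE)
}

#' @export
print.scale_correction <- function(x, ...) {
  cat(sprintf("<scale_correction> alpha = %.4f (lambda <= %g nm, %d points)\n",
              x$alpha, x$lambda_max_nm, x$n_points))
  invisible(x)
}

#' Apply the intensity correction to a reflectance cube
#'
#' @param cube A [band_cube()] in reflectance units.
#' @param sc A `scale_correction` from [fit_alpha()], or a bare positive
#'   scalar.
#' @return The uniformly scaled cube, provenance appended.
#' @export
apply_alpha <- function(cube, sc) {
  alpha <- if (inherits(sc, "scale_correction")) sc$alpha else as.numeric(sc)
  stopifnot(is.finite(alpha), alpha > 0)
  if (cube$unit != "reflectance") {
    stop("intensity correction applies to reflectance cubes", call. = FALSE)
  }
  cube$data <- cube$data * alpha
  cube_note(cube, sprintf("alpha=%.6g", alpha))
}

#' Validate a calibrated cube against the reference chart
#'
#' Per tile, the spatial mean spectrum at the band centers is compared with
#' the chart resampled to those centers: the difference
#' `d = reconstructed - reference`, a within-SD flag (|d| within the
#' reference SD plus the measured spatial SD), and RMSE summaries over the
#' spectral regions delimited by `region_breaks_nm` (visible / low NIR /
#' high NIR).
#'
#' @param cube A calibrated [band_cube()] in reflectance units.
#' @param chart A [reference_chart()].
#' @param tile_masks Named list of logical masks (cube resolution), one per
#'   tile.
#' @param region_breaks_nm Two wavelengths splitting the spectrum into three
#'   validation regions.
#' @return A `validation_report`: `points` tibble (tile, wavelength_nm,
#'   measured, reference, d, sd_reference, sd_measured, n, within_sd,
#'   region) and `rmse` tibble (region, rmse, n).
#' @export
validate_against_chart <- function(cube, chart, tile_masks,
                                   region_breaks_nm = c(680, 850)) {
  spectra <- extract_tile_spectra(cube, tile_masks)
  spectra <- spectra[spectra$tile %in% chart$tile_names, ]
  if (!nrow(spectra)) stop("no mask matches a chart tile", call. = FALSE)
  ref <- vapply(seq_len(nrow(spectra)), function(i) {
    curve_at(chart_tile_curve(chart, spectra$tile[i]),
             spectra$wavelength_nm[i])
  }, numeric(1))
  sd_ref <- vapply(seq_len(nrow(spectra)), function(i) {
    stats::approx(chart$grid, chart$sd[spectra$tile[i], ],
                  xout = spectra$wavelength_nm[i], rule = 2)$y
  }, numeric(1))
  d <- spectra$value - ref
  region <- cut(spectra$wavelength_nm,
                breaks = c(-Inf, region_breaks_nm, Inf),
                labels = c("visible", "nir_low", "nir_high"))
  pts <- tibble::tibble(
    tile = spectra$tile, wavelength_nm = spectra$wavelength_nm,
    measured = spectra$value, reference = ref, d = d,
    sd_reference = sd_ref, sd_measured = spectra$sd, n = spectra$n,
    within_sd = abs(d) <= sd_ref + ifelse(is.na(spectra$sd), 0, spectra$sd),
    region = as.character(region))
  ok <- is.finite(pts$d)
  rmse <- do.call(rbind, lapply(split(pts[ok, ], pts$region[ok]), function(g) {
    tibble::tibble(region = g$region[1], rmse = sqrt(mean(g$d^2)),
                   n = nrow(g))
  }))
  structure(list(points = pts, rmse = rmse,
                 region_breaks_nm = region_breaks_nm),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (i in seq_len(nrow(x$rmse))) {
    cat(sprintf("  %-8s RMSE = %.4f (%d points)\n", x$rmse$region[i],
                x$rmse$rmse[i], x$rmse$n[i]))
  }
  cat(sprintf("  within SD: %.1f%%\n",
              100 * mean(x$points$within_sd, na.rm = TRUE)))
  invisible(x)
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$points

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  out <- as.list(stats::setNames(x$rmse$rmse, paste0("rmse_", x$rmse$region)))
  out$frac_within_sd <- mean(x$points$within_sd, na.rm = TRUE)
  out$n_points <- nrow(x$points)
  tibble::as_tibble(out)
}

#' @method tidy scale_correction
#' @export
tidy.scale_correction <- function(x, ...) {
  tibble::tibble(term = "alpha", estimate = x$alpha,
                 lambda_max_nm = x$lambda_max_nm, n_points = x$n_points,
                 setup = x$setup_name, illumination = x$illumination_kind)
}

#' Difference-versus-reference plot of a validation report
#'
#' The per-tile gap `d` between reconstructed and reference reflectance as a
#' function of wavelength, with the pooled reference-SD envelope.
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$wavelength_nm, y = .data$d)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = -.data$sd_reference,
                                      ymax = .data$sd_reference),
                         fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tile), size = 1,
                        show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = object$region_breaks_nm,
                        linetype = 3, colour = "grey40") +
    ggplot2::labs(x = "wavelength (nm)",
                  y = "d = reconstructed - reference")
}
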