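#' Illumination spectra
#'
#' Relative radiometric power of the supported light sources on the working
#' grid. Both physical sources clip at 400 nm to avoid UV illumination.
#'
#' * `xenon` — broad, nearly flat from 400 nm through the NIR, with a group
#'   of narrow intensity peaks between 810 and 845 nm.
#' * `led` — surgical LED: strong peak at 460 nm, elevated plateau over
#'   525-680 nm, intensity decreasing rapidly above 680 nm, leaving very low
#'   NIR power.
#' * `flat` — unit power everywhere (idealized reference).
#'
#' @param kind One of `"xenon"`, `"led"`, `"flat"`.
#' @param grid Wavelength grid (default [working_grid()]).
#' @return An `illumination_spectrum`: a [spectral_curve()] with a `kind`
#'   attribute.
#' @export
make_illumination <- function(kind = c("xenon", "led", "flat"),
                              grid = working_grid()) {
  kind <- match.arg(kind)
  v <- switch(kind,
    flat = rep(1, length(grid)),
    xenon = {
      base <- ifelse(grid >= 400, 1, 0)
      peaks <- 0.6 * exp(-((grid - 820)^2) / (2 * 4^2)) +
               0.8 * exp(-((grid - 828)^2) / (2 * 3^2)) +
               0.5 * exp(-((grid - 840)^2) / (2 * 4^2))
      base * (1 + peaks)
    },
    led = {
      # the surgical LED's luminous flux is far higher than the xenon
      # source's (hence the ~100x shorter exposures); scale ~130x
      peak <- 3.0 * exp(-((grid - 460)^2) / (2 * 14^2))
      plateau <- 0.8 / ((1 + exp(-(grid - 520) / 8)) *
                        (1 + exp((grid - 680) / 12)))
      floor_nir <- 0.01 * exp(-pmax(grid - 680, 0) / 150)
      ifelse(grid >= 400, 130 * (peak + plateau + floor_nir), 0)
    })
  out <- spectral_curve(grid, v)
  attr(out, "kind") <- kind
  class(out) <- c("illumination_spectrum", class(out))
  out
}

illumination_kind <- function(x) attr(x, "kind")
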