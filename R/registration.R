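#' Normalized cross-correlation of two images
#'
#' Zero-mean, unit-variance correlation in \[-1, 1\]; invariant to affine
#' intensity maps with positive gain. Used as the registration cost.
#'
#' @param a,b Equal-shaped 2-D images with nonzero variance.
#' @return The NCC score.
#' @export
ncc_score <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("images must share shape", call. = FALSE)
  av <- as.vector(a); bv <- as.vector(b)
  ok <- is.finite(av) & is.finite(bv)
  av <- av[ok]; bv <- bv[ok]
  sa <- stats::sd(av); sb <- stats::sd(bv)
  if (!length(av) || sa == 0 || sb == 0) {
    stop("undefined correlation: constant image", call. = FALSE)
  }
  mean((av - mean(av)) * (bv - mean(bv))) / (sa * sb) *
    length(av) / (length(av) - 1L)
}

#' Estimate the integer translation between two images
#'
#' Exhaustive search over all integer shifts up to `max_shift`, scoring each
#' candidate by NCC on the valid-overlap region only (no zero padding). Ties
#' are broken by the smallest shift norm, then row-major order. The returned
#' `(dy, dx)` is the displacement of `moving` relative to `ref`
#' (`moving[y, x] == ref[y - dy, x - dx]`); translating `moving` back by the
#' negated shift aligns it onto `ref`.
#'
#' @param ref,moving 2-D images.
#' @param max_shift Maximum |dy|, |dx| searched.
#' @return A `shift_vector`: list with integer `dy`, `dx` and the NCC
#'   `score` at the optimum.
#' @export
register_translation <- function(ref, moving, max_shift = 8L) {
  max_shift <- as.integer(max_shift)
  h <- nrow(ref); w <- ncol(ref)
  if (!identical(dim(ref), dim(moving))) {
    stop("images must share shape", call. = FALSE)
  }
  if (h - max_shift < 16L || w - max_shift < 16L) {
    stop("overlap at max_shift below 16 x 16 pixels", call. = FALSE)
  }
  best <- NULL
  for (dy in -max_shift:max_shift) {
    ys_r <- max(1L, 1L - dy):min(h, h - dy)
    ys_m <- ys_r + dy
    for (dx in -max_shift:max_shift) {
      xs_r <- max(1L, 1L - dx):min(w, w - dx)
      xs_m <- xs_r + dx
      s <- tryCatch(ncc_score(ref[ys_r, xs_r, drop = FALSE],
                              moving[ys_m, xs_m, drop = FALSE]),
                    error = function(e) -Inf)
      cand <- list(dy = dy, dx = dx, score = s, norm = dy^2 + dx^2)
      if (is.null(best) || s > best$score + 1e-12 ||
          (abs(s - best$score) <= 1e-12 &&
           (cand$norm < best$norm ||
            (cand$norm == best$norm &&
             (dy < best$dy || (dy == best$dy && dx < best$dx)))))) {
        best <- cand
      }
    }
  }
  structure(list(dy = best$dy, dx = best$dx, score = best$score),
            class = "shift_vector")
}

#' @export
print.shift_vector <- function(x, ...) {
  cat(sprintf("<shift_vector> (dy, dx) = (%d, %d), NCC = %.4f\n",
              x$dy, x$dx, x$score))
  invisible(x)
}

# Translate an image by an integer shift, NA-filling uncovered pixels.
shift_image <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  ys_t <- max(1L, 1L + dy):min(h, h + dy)
  xs_t <- max(1L, 1L + dx):min(w, w + dx)
  out[ys_t, xs_t] <- img[ys_t - dy, xs_t - dx]
  out
}

#' Register band cubes and assemble the joint hypercube
#'
#' Aligns the contributing cubes (integer translation, NCC cost) and merges
#' their bands sorted by center wavelength with a per-band source tag. The
#' two snapshot cameras (16 + 25 bands) assemble into the 41-band hypercube
#' used for tissue visualization.
#'
#' Inter-cube offsets are estimated between the spectrally closest pair of
#' bands of the two cubes (scene content decorrelates across distant
#' wavelengths, making NCC between spectrally remote bands unreliable) and
#' applied rigidly to the whole cube. With `per_band = TRUE` each band is
#' additionally registered to its own cube's reference band — for
#' sequentially acquired stacks whose frames may drift individually.
#'
#' @param cubes List of [band_cube()]s sharing spatial size, same unit.
#' @param ref_band_per_cube Optional integer vector: the intra-cube
#'   reference band of each cube (default: its mid-wavelength band). The
#'   first cube anchors the global frame.
#' @param max_shift Search radius for the registration.
#' @param per_band Also register every band to its own cube's reference
#'   band?
#' @return A [band_cube()] whose bandset is the concatenation sorted by
#'   center wavelength with a `source` column; attribute `shifts` records
#'   the per-band displacements.
#' @export
assemble_hypercube <- function(cubes, ref_band_per_cube = NULL,
                               max_shift = 8L, per_band = FALSE) {
  stopifnot(length(cubes) >= 1L)
  dims <- lapply(cubes, function(cc) dim(cc$data)[2:3])
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("cubes must share spatial size", call. = FALSE)
  }
  units <- unique(vapply(cubes, function(cc) cc$unit, character(1)))
  if (length(units) != 1L) stop("cubes must share a unit", call. = FALSE)
  if (is.null(ref_band_per_cube)) {
    ref_band_per_cube <- vapply(cubes, function(cc) {
      as.integer(ceiling(n_bands(cc$bandset) / 2))
    }, integer(1))
  }
  planes <- list(); centers <- numeric(); fwhms <- numeric()
  sources <- character(); shifts <- list()
  for (k in seq_along(cubes)) {
    cc <- cubes[[k]]
    rigid <- if (k == 1L) {
      list(dy = 0L, dx = 0L)
    } else {
      # anchor on the spectrally closest band pair between cube 1 and cube k
      pair <- which(outer(cubes[[1]]$bandset$center_nm,
                          cc$bandset$center_nm,
                          function(a, b) abs(a - b)) ==
                    min(abs(outer(cubes[[1]]$bandset$center_nm,
                                  cc$bandset$center_nm, "-"))),
                    arr.ind = TRUE)[1, ]
      register_translation(cubes[[1]]$data[pair[1], , ],
                           cc$data[pair[2], , ], max_shift = max_shift)
    }
    own_ref <- cc$data[ref_band_per_cube[k], , ]
    for (b in seq_len(n_bands(cc$bandset))) {
      mov <- cc$data[b, , ]
      fine <- if (per_band && b != ref_band_per_cube[k]) {
        register_translation(own_ref, mov, max_shift = max_shift)
      } else {
        list(dy = 0L, dx = 0L)
      }
      dy <- rigid$dy + fine$dy; dx <- rigid$dx + fine$dx
      planes[[length(planes) + 1L]] <- shift_image(mov, -dy, -dx)
      centers <- c(centers, cc$bandset$center_nm[b])
      fwhms <- c(fwhms, cc$bandset$fwhm_nm[b])
      sources <- c(sources, band_setup(cc$bandset))
      shifts[[length(shifts) + 1L]] <- c(dy = dy, dx = dx)
    }
  }
  if (anyDuplicated(centers)) {
    stop("duplicate band centers across cubes", call. = FALSE)
  }
  # each plane's valid set is a rectangle (translation-only NA borders);
  # the common region is the intersection of those rectangles
  row_lo <- 1L; row_hi <- dims[[1]][1]; col_lo <- 1L; col_hi <- dims[[1]][2]
  for (p in planes) {
    ok <- !is.na(p)
    vr <- which(apply(ok, 1, any)); vc <- which(apply(ok, 2, any))
    if (!length(vr) || !length(vc)) {
      stop("no common valid region after registration", call. = FALSE)
    }
    row_lo <- max(row_lo, min(vr)); row_hi <- min(row_hi, max(vr))
    col_lo <- max(col_lo, min(vc)); col_hi <- min(col_hi, max(vc))
  }
  if (row_lo > row_hi || col_lo > col_hi) {
    stop("no common valid region after registration", call. = FALSE)
  }
  rows <- row_lo:row_hi; cols <- col_lo:col_hi
  ord <- order(centers)
  nb <- length(ord)
  data <- array(NA_real_, dim = c(nb, length(rows), length(cols)))
  for (i in seq_len(nb)) {
    data[i, , ] <- planes[[ord[i]]][rows, cols, drop = FALSE]
  }
  bs <- band_set("hypercube", centers[ord], fwhms[ord], 0:(nb - 1L),
                 pattern = 1L)
  bs$source <- sources[ord]
  out <- band_cube(data, bs, units,
                   provenance = c(unlist(lapply(cubes, function(cc)
                     cc$provenance)), "assemble_hypercube"))
  attr(out, "shifts") <- do.call(rbind, shifts)[ord, , drop = FALSE]
  out
}
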