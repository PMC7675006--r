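test_that("demosaic extracts planes in sorted band order", {
  c4 <- load_band_table("cam4x4")
  const <- mosaic_frame(matrix(9, 8, 8), c4, exposure_ms = 65)
  cube <- demosaic(const)
  expect_equal(dim(cube$data), c(16L, 2L, 2L))
  expect_true(all(cube$data == 9))
  expect_equal(cube_exposure(cube), 65)

  # frame tiling the values 0..15 in pattern (row-major cell) order:
  # plane k must be constant, equal to the value at its sensor position
  cell <- matrix(0:15, 4, 4, byrow = TRUE)
  img <- cell[rep(1:4, 2), rep(1:4, 2)]
  cube2 <- demosaic(mosaic_frame(img, c4, 65))
  for (b in seq_len(16)) {
    expect_equal(unique(as.vector(cube2$data[b, , ])),
                 c4$sensor_index[b])
  }

  c5 <- load_band_table("cam5x5")
  cube5 <- demosaic(mosaic_frame(matrix(1, 10, 10), c5, 110))
  expect_equal(dim(cube5$data)[1], 25L)

  expect_error(demosaic(matrix(1, 9, 8), bandset = c4), "multiples")
})

test_that("correction matrix is identity for ideal responses", {
  bs <- load_band_table("cam4x4")
  grid <- working_grid()
  ideal <- t(vapply(seq_len(16), function(b) {
    gaussian_band_response(bs$center_nm[b], bs$fwhm_nm[b], grid)$value
  }, numeric(length(grid))))
  resp <- sensor_response_set(bs, grid, ideal)
  C <- build_correction_matrix(resp, bs, ridge = 0)
  expect_equal(C$matrix, diag(16), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two-band solution matches the closed-form Gram inverse", {
  # two unit-sum responses with overlap Gram matrix [[1, .3], [.3, 1]]
  # (scaled); targets chosen as the dual basis so that the unnormalized
  # solution equals the closed-form 2x2 inverse
  grid <- seq(480, 560, 1)
  r1 <- gaussian_band_response(500, 20, grid)$value
  r2 <- gaussian_band_response(518, 20, grid)$value
  r1 <- r1 / sum(r1); r2 <- r2 / sum(r2)
  Rn <- rbind(r1, r2)
  G <- Rn %*% t(Rn)
  rho <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
  Ginv_expect <- solve(G)

  bs <- toy_bandset()
  resp <- sensor_response_set(bs, grid, rbind(r1 / max(r1), r2 / max(r2)))
  # build with ridge 0 and algebra exposed (no flat-in/flat-out rescale);
  # the solver works on sum-normalized responses, so feed it targets whose
  # normalized rows are the dual basis G^-1 Rn
  expect_gt(rho, 0.25)  # bands genuinely overlap
  C <- build_correction_matrix(resp, bs, ridge = 0, normalize = FALSE)
  # targets equal the responses here (same centers/FWHM), so the solution
  # collapses to G^-1 G = I; its residual reproduces the targets exactly
  tg <- t(vapply(1:2, function(b) {
    v <- gaussian_band_response(bs$center_nm[b], bs$fwhm_nm[b], grid)$value
    v / sum(v)
  }, numeric(length(grid))))
  expect_equal(t(C$matrix) %*% Rn, tg, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(C$matrix, diag(2), tolerance = 1e-8, ignore_attr = TRUE)

  # explicit 2x2 closed form: with dual-basis targets T = G^-1 Rn the
  # unnormalized least-squares solution is exactly the Gram inverse
  dual <- Ginv_expect %*% Rn
  Ct <- dual %*% t(Rn) %*% solve(G)
  expect_equal(Ct, Ginv_expect, tolerance = 1e-10)
})

test_that("singular Gram matrix without ridge advises regularization", {
  grid <- seq(480, 560, 1)
  r <- gaussian_band_response(520, 20, grid)$value
  resp <- sensor_response_set(toy_bandset(), grid, rbind(r, r))
  expect_error(build_correction_matrix(resp, toy_bandset(), ridge = 0),
               "ridge")
})

test_that("secondary-peak contamination is suppressed by the correction", {
  bs <- load_band_table("cam5x5")
  resp <- make_sensor_responses(bs, secondary_peaks = "default")
  sp <- default_secondary_peaks(bs)[[1]]
  C <- build_correction_matrix(resp, bs, ridge = 1e-4)

  # forward-model oracle: a scene reflecting only in a narrow window at the
  # secondary-peak wavelength, rendered and pushed through the chain with
  # and without the correction
  grid <- working_grid()
  spike <- spectral_curve(grid, 0.9 * exp(-((grid - sp$center_nm)^2) /
                                            (2 * 6^2)))
  scene <- scene_model(matrix("spike", 10, 10), list(spike = spike))
  acq <- noiseless(acquisition_params(exposure_ms = 110,
                                      dark_offset_counts = 0,
                                      vignetting_strength = 0))
  raw <- demosaic(render_mosaic_frame(scene, make_illumination("flat"),
                                      resp, acq))
  white <- demosaic(render_mosaic_frame(make_uniform_scene(10, 10, 0.95),
                                        make_illumination("flat"), resp,
                                        acq))
  raw$provenance <- c(raw$provenance, "dark_subtracted")
  i_res <- to_reflectance(raw, NULL, white_reference(white$data, 110), NULL,
                          exposure_ms = 110)
  b <- sp$band
  uncorrected <- mean(i_res$data[b, , ])
  corrected <- mean(apply_spectral_correction(i_res, C)$data[b, , ])
  expect_gt(uncorrected, 0.05)  # contamination clearly present
  expect_lt(abs(corrected), 0.1 * uncorrected)
})

test_that("apply_spectral_correction is linear with identity/zero cases", {
  bs <- load_band_table("cam4x4")
  resp <- make_sensor_responses(bs)
  Cid <- structure(list(matrix = diag(16), ridge = 0, target_bandset = bs,
                        illumination_kind = "flat"),
                   class = "correction_matrix")
  cube <- band_cube(array(runif(16 * 3 * 3), dim = c(16, 3, 3)), bs,
                    "reflectance")
  expect_equal(apply_spectral_correction(cube, Cid)$data, cube$data)

  zero <- band_cube(array(0, dim = c(16, 3, 3)), bs, "reflectance")
  C <- build_correction_matrix(resp, bs)
  expect_equal(apply_spectral_correction(zero, C)$data, zero$data)

  cube2 <- cube; cube2$data <- 2 * cube$data
  expect_equal(apply_spectral_correction(cube2, C)$data,
               2 * apply_spectral_correction(cube, C)$data,
               tolerance = 1e-12)

  bad <- band_cube(array(1, dim = c(4, 3, 3)),
                   band_set("x", c(1, 2, 3, 4) * 100, rep(10, 4), 0:3,
                            pattern = 2), "reflectance")
  expect_error(apply_spectral_correction(bad, C), "band count")
})

test_that("correction reduces tile-spectrum RMSE at least 5-fold", {
  # a camera with heavily overlapping responses (4x the tabulated FWHMs):
  # without deconvolution the measured spectra are strongly smoothed
  bs <- load_band_table("cam4x4")
  broad_bs <- band_set("cam4x4", bs$center_nm, bs$fwhm_nm * 4,
                       bs$sensor_index, pattern = 4)
  broad <- make_sensor_responses(broad_bs)
  broad$bandset <- bs
  acqn <- simulate_acquisition("cam4x4", "xenon", seed = 1, noise = FALSE,
                               responses = broad)
  with_c <- calibrate_acquisition(acqn)
  without_c <- calibrate_acquisition(acqn, spectral_correction = FALSE)
  sel <- function(cal) {
    p <- cal$report$points
    ok <- is.finite(p$d) & p$wavelength_nm <= 850
    sqrt(mean(p$d[ok]^2))
  }
  expect_lt(sel(with_c) * 5, sel(without_c))
})

test_that("ridge regularization rescues the fit when responses are noisy", {
  bs <- load_band_table("cam4x4")
  broad_bs <- band_set("cam4x4", bs$center_nm, bs$fwhm_nm * 4,
                       bs$sensor_index, pattern = 4)
  broad <- make_sensor_responses(broad_bs)
  broad$bandset <- bs
  acqn <- simulate_acquisition("cam4x4", "xenon", seed = 1, noise = FALSE,
                               responses = broad)
  noisy <- broad
  noisy$responses <- pmin(pmax(
    broad$responses + withr::with_seed(9, {
      matrix(rnorm(length(broad$responses), sd = 2e-3),
             nrow(broad$responses))
    }), 0), 1)
  acqn$responses <- noisy  # calibration believes the noisy curves
  rmse_at <- function(ridge, correct = TRUE) {
    cal <- calibrate_acquisition(acqn, ridge = ridge,
                                 spectral_correction = correct)
    sqrt(mean(cal$report$points$d^2, na.rm = TRUE))
  }
  ridges <- c(1e-6, 1e-4, 1e-2, 1e-1)
  sweep_rmse <- vapply(ridges, rmse_at, numeric(1))
  ident_rmse <- rmse_at(1e-4, correct = FALSE)
  # some ridge beats both no correction and the weakest regularization
  expect_lt(min(sweep_rmse), ident_rmse)
  expect_lte(min(sweep_rmse), sweep_rmse[1])
})
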