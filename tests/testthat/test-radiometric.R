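test_that("average_dark computes temporal mean and SD", {
  f7 <- replicate(10, matrix(7, 4, 4), simplify = FALSE)
  d <- average_dark(f7, exposure_ms = 10)
  expect_equal(d$mean_frame, matrix(7, 4, 4))
  expect_equal(d$noise_sd, matrix(0, 4, 4))

  alt <- c(replicate(5, matrix(4, 4, 4), simplify = FALSE),
           replicate(5, matrix(6, 4, 4), simplify = FALSE))
  expect_equal(average_dark(alt, 10)$mean_frame, matrix(5, 4, 4))

  one <- average_dark(list(matrix(3, 2, 2)), 10)
  expect_true(one$sd_degenerate)

  expect_error(average_dark(list(matrix(1, 2, 2), matrix(1, 3, 3)), 10),
               "shape")

  # sampling-distribution oracle: 500 Gaussian frames, offset 10, SD 2
  frames <- withr::with_seed(5, replicate(500, {
    matrix(rnorm(16, mean = 10, sd = 2), 4, 4)
  }, simplify = FALSE))
  d <- average_dark(frames, 10)
  expect_true(all(abs(d$mean_frame - 10) < 0.3))
  expect_true(all(abs(d$noise_sd - 2) < 0.2))
})

test_that("flat-field gain inverts a known vignetting profile", {
  bs <- toy_bandset()
  uni <- band_cube(array(500, dim = c(2, 31, 31)), bs, "counts")
  g <- estimate_flat_field(uni, center_window_px = 5)
  expect_equal(g$gain, array(1, dim = c(2, 31, 31)), tolerance = 1e-12)

  # a pixel at twice the reference intensity gets gain 0.5
  bright <- uni
  bright$data[1, 1, 1] <- 1000
  g2 <- estimate_flat_field(bright, center_window_px = 5)
  expect_equal(g2$gain[1, 1, 1], 0.5, tolerance = 1e-9)

  expect_error(estimate_flat_field(uni, center_window_px = 40), "window")

  # forward-model inversion: quartic vignetting, strength 0.3
  resp <- make_sensor_responses(load_band_table("cam4x4"))
  acq <- noiseless(acquisition_params(exposure_ms = 65,
                                      dark_offset_counts = 0,
                                      vignetting_strength = 0.3))
  white <- render_mosaic_frame(make_uniform_scene(84, 84, 0.95),
                               make_illumination("xenon"), resp, acq)
  wc <- demosaic(white)
  gain <- estimate_flat_field(wc, center_window_px = 3)
  flat <- apply_flat_field(wc, gain)
  for (b in c(1, 9, 16)) {
    plane <- flat$data[b, , ]
    expect_equal(plane[1, 1] / plane[10, 10], 1, tolerance = 1e-6)
  }
})

test_that("apply_flat_field is element-wise and checks shape", {
  bs <- toy_bandset()
  cube <- band_cube(array(runif(2 * 4 * 4), dim = c(2, 4, 4)), bs, "counts")
  g1 <- structure(list(gain = array(1, dim = c(2, 4, 4)),
                       center_window_px = 1, masked_frac = 0),
                  class = "flat_field_gain")
  expect_equal(apply_flat_field(cube, g1)$data, cube$data)
  g2 <- g1; g2$gain <- array(2, dim = c(2, 4, 4))
  expect_equal(apply_flat_field(cube, g2)$data, 2 * cube$data)
  g3 <- g1; g3$gain <- array(1, dim = c(3, 4, 4))
  expect_error(apply_flat_field(cube, g3), "shape")
})

test_that("reflectance conversion implements the one-point formula", {
  bs <- toy_bandset()
  mk_cube <- function(v, expo) {
    cc <- band_cube(array(v, dim = c(2, 4, 4)), bs, "counts")
    attr(cc, "exposure_ms") <- expo
    cc
  }
  dark <- average_dark(list(matrix(100, 4, 4)), exposure_ms = 10)

  # hand evaluation: (600 - 100) / (1100 - 100) * 2 = 1.0
  raw <- mk_cube(600, 10)
  white <- white_reference(matrix(1100, 4, 4), exposure_ms = 20)
  res <- to_reflectance(raw, dark, white, dark)
  expect_equal(unique(as.vector(res$data)), 1.0)
  expect_equal(res$unit, "reflectance")

  # self-reference gives exactly 1
  raww <- mk_cube(1100, 20)
  expect_equal(unique(as.vector(to_reflectance(raww, dark, white,
                                               dark)$data)), 1.0)

  # raw equal to the dark mean gives exactly 0
  expect_equal(unique(as.vector(to_reflectance(mk_cube(100, 10), dark,
                                               white, dark)$data)), 0)

  # exposure invariance: halving the raw exposure (and the noiseless signal
  # with it) leaves the result unchanged to 1e-9
  raw_half <- mk_cube(100 + (600 - 100) / 2, 5)
  res_half <- to_reflectance(raw_half, dark, white, dark)
  expect_equal(res_half$data, res$data, tolerance = 1e-9)

  # board-reflectance option
  res_b <- to_reflectance(raw, dark, white, dark,
                          apply_board_reflectance = TRUE)
  expect_equal(unique(as.vector(res_b$data)), 0.95)

  # masked non-positive denominator
  wbad <- white_reference(matrix(c(50, rep(1100, 15)), 4, 4),
                          exposure_ms = 20)
  res_bad <- to_reflectance(raw, dark, wbad, dark)
  expect_true(all(is.na(res_bad$data[, 1, 1])))

  expect_error(to_reflectance(band_cube(array(1, dim = c(2, 4, 4)), bs,
                                        "counts"), dark, white, dark),
               "exposure")
})

test_that("SNR follows amplitude over dark-noise SD", {
  dark <- average_dark(withr::with_seed(2, replicate(200, {
    matrix(rnorm(64, 10, 2), 8, 8)
  }, simplify = FALSE)), 10)
  expect_equal(compute_snr(100, dark), 50, tolerance = 0.1)
  expect_equal(compute_snr(0, dark), 0)

  d0 <- average_dark(list(matrix(5, 4, 4), matrix(5, 4, 4)), 10)
  expect_error(compute_snr(10, d0), "undefined")
})

test_that("simulated LED NIR band has lower SNR than a visible band", {
  cal5 <- calibrate_acquisition(
    simulate_acquisition("cam5x5", "led", seed = 2, noise = TRUE,
                         n_dark = 30))
  cal4 <- calibrate_acquisition(
    simulate_acquisition("cam4x4", "led", seed = 2, noise = TRUE,
                         n_dark = 30))
  snr_nir <- cal5$snr[which.max(cal5$cube$bandset$center_nm)]
  snr_vis <- cal4$snr[which(cal4$cube$bandset$center_nm == 543)]
  expect_lt(snr_nir, snr_vis)
})

test_that("alpha fit recovers injected scale factors", {
  ch <- make_reference_chart(seed = 1)

  ident <- attenuated_chart_spectra(ch, 1)
  expect_equal(fit_alpha(ident, ch)$alpha, 1.0, tolerance = 1e-12)

  m <- attenuated_chart_spectra(ch, 2.01)
  expect_equal(fit_alpha(m, ch)$alpha, 2.01, tolerance = 1e-9)

  # corrupted NIR excluded by the 850 nm cutoff
  m2 <- attenuated_chart_spectra(ch, 1.22, corrupt_above_nm = 850)
  expect_equal(fit_alpha(m2, ch)$alpha, 1.22, tolerance = 1e-9)
  # without the cutoff the corruption must bias the fit
  expect_gt(abs(fit_alpha(m2, ch, lambda_max_nm = 1000)$alpha - 1.22), 0.01)

  # scale equivariance: scaling measurements by k scales alpha by 1/k
  a1 <- fit_alpha(m, ch)$alpha
  mk <- lapply(m, function(sc) spectral_curve(sc$wavelength_nm,
                                              sc$value * 3))
  expect_equal(fit_alpha(mk, ch)$alpha, a1 / 3, tolerance = 1e-9)

  expect_error(fit_alpha(list(nonsense = spectral_curve(500, 1)), ch),
               "no measured tile")
})

test_that("apply_alpha scales uniformly and closes the loop", {
  bs <- toy_bandset()
  cube <- band_cube(array(0.3, dim = c(2, 4, 4)), bs, "reflectance")
  expect_equal(apply_alpha(cube, 1)$data, cube$data)
  expect_equal(unique(as.vector(apply_alpha(cube, 2)$data)), 0.6)
  expect_error(apply_alpha(band_cube(array(1, dim = c(2, 4, 4)), bs,
                                     "counts"), 2), "reflectance")

  # round trip: fit on attenuated spectra, apply, residual ~ 0
  ch <- make_reference_chart(seed = 1)
  m <- attenuated_chart_spectra(ch, 2.01)
  sc <- fit_alpha(m, ch)
  for (t in c("red", "cyan", "neutral 8")) {
    corrected <- m[[t]]$value * sc$alpha
    expect_equal(corrected, ch$reflectance[t, ], tolerance = 1e-9)
  }
})

test_that("chart validation reports d, SD flags and regional RMSE", {
  ch <- make_reference_chart(seed = 4)
  bs <- load_band_table("cam4x4")
  # build an exact cube straight from the chart at band centers
  masks <- scene_tile_masks(make_chart_scene(ch, tile_px = 2), pattern = 1)
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  data <- array(0, dim = c(nrow(bs), h, w))
  for (t in ch$tile_names) {
    vals <- curve_at(chart_tile_curve(ch, t), bs$center_nm)
    for (b in seq_len(nrow(bs))) data[b, , ][masks[[t]]] <- vals[b]
  }
  cube <- band_cube(data, bs, "reflectance")
  rep0 <- validate_against_chart(cube, ch, masks)
  expect_lt(max(abs(rep0$points$d)), 1e-9)
  expect_true(all(rep0$points$within_sd))
  expect_equal(unique(rep0$points$region), "visible")

  cube2 <- cube; cube2$data <- cube$data + 0.05
  rep2 <- validate_against_chart(cube2, ch, masks)
  md <- tapply(rep2$points$d, rep2$points$tile, mean)
  expect_equal(as.vector(md), rep(0.05, 24), tolerance = 1e-9)

  expect_error(validate_against_chart(cube, ch,
                                      list(red = matrix(FALSE, h, w))),
               "empty mask")
})

test_that("noisy renders stay within 3 SD envelopes for >= 95% of points", {
  hits <- 0L; total <- 0L
  for (seed in 1:8) {
    acqn <- simulate_acquisition("cam4x4", "xenon", seed = seed,
                                 noise = TRUE, n_dark = 30)
    cal <- calibrate_acquisition(acqn)
    pts <- cal$report$points
    sem <- pts$sd_measured / sqrt(pts$n)
    ok <- abs(pts$d) <= 3 * (pts$sd_reference + sem)
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.95)
})
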