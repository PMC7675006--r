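test_that("synthetic reference chart has the chart's structure", {
  ch <- make_reference_chart(seed = 7)
  expect_s3_class(ch, "reference_chart")
  expect_length(ch$tile_names, 24L)
  expect_equal(ncol(ch$reflectance), 62L)   # (1000 - 390) / 10 + 1
  expect_true(all(ch$reflectance >= 0 & ch$reflectance <= 1))
  expect_true(all(ch$sd >= 0))

  # gray tiles are flat; colored are not
  gray <- c("white 9.5", "neutral 8", "neutral 6.5", "neutral 5",
            "neutral 3.5", "black 2")
  for (g in gray) expect_equal(sd(ch$reflectance[g, ]), 0)
  expect_gt(sd(ch$reflectance["red", ]), 0)

  # seeding contract: gray identical, colored differ across seeds
  ch2 <- make_reference_chart(seed = 8)
  expect_equal(ch2$reflectance[gray, ], ch$reflectance[gray, ])
  expect_false(isTRUE(all.equal(ch2$reflectance["red", ],
                                ch$reflectance["red", ])))

  # SD envelope grows from ~0.002 in the visible to ~0.11 in the NIR
  expect_lt(max(ch$sd[, ch$grid <= 600]), 0.01)
  expect_gt(max(ch$sd[, ch$grid >= 990]), 0.1)
})

test_that("illumination spectra have the stated shapes", {
  led <- make_illumination("led")
  expect_lt(curve_at(led, 900), 0.1 * curve_at(led, 460))
  expect_true(all(led$value[led$wavelength_nm < 400] == 0))

  xe <- make_illumination("xenon")
  sel <- xe$wavelength_nm >= 400 & xe$wavelength_nm <= 850
  expect_true(all(xe$value[sel] > 0))
  expect_true(all(xe$value[xe$wavelength_nm < 400] == 0))
  # NIR peaks between 810 and 845 nm
  base <- curve_at(xe, 700)
  expect_gt(max(curve_at(xe, 810:845)), 1.3 * base)

  flat <- make_illumination("flat")
  expect_true(all(flat$value == 1))
  expect_error(make_illumination("sun"), "arg")
})

test_that("synthetic sensor responses carry the per-band peak gaps", {
  c4 <- make_sensor_responses(load_band_table("cam4x4"))
  expect_equal(nrow(c4$responses), 16L)
  peaks <- apply(c4$responses, 1, max)
  expect_equal(sort(unique(round(peaks, 3))), c(0.1, 0.2))
  expect_equal(sum(round(peaks, 3) == 0.1), 1L)  # one low band
  # unimodal without secondaries: one sign change of the difference
  for (b in c(1, 8, 16)) {
    d <- diff(c4$responses[b, ])
    expect_lte(sum(diff(sign(d[d != 0])) != 0), 1L)
  }

  c5 <- make_sensor_responses(load_band_table("cam5x5"))
  expect_lte(max(c5$responses), 0.12)

  # a secondary peak makes exactly two local maxima
  sec <- make_sensor_responses(load_band_table("cam5x5"),
                               secondary_peaks = "default")
  b <- default_secondary_peaks(load_band_table("cam5x5"))[[1]]$band
  r <- sec$responses[b, ]
  interior <- which(diff(sign(diff(r))) == -2) + 1L
  maxima <- r[interior][r[interior] > 1e-6]
  expect_length(maxima, 2L)

  expect_error(
    make_sensor_responses(load_band_table("cam4x4"),
                          secondary_peaks = list(list(band = 1,
                                                      center_nm = 500,
                                                      height = 1.5))),
    "below the primary")
})

test_that("mosaic render matches a hand-summed quadrature oracle", {
  bs <- load_band_table("cam4x4")
  resp <- make_sensor_responses(bs)
  scene <- make_uniform_scene(8, 8, reflectance = 1)
  acq <- noiseless(acquisition_params(exposure_ms = 10,
                                      dark_offset_counts = 0,
                                      vignetting_strength = 0,
                                      gain_counts = 3))
  fr <- render_mosaic_frame(scene, make_illumination("flat"), resp, acq)
  cube <- demosaic(fr)
  step <- diff(resp$grid)[1]
  for (b in seq_len(16)) {
    oracle <- 0
    for (i in seq_along(resp$grid)) {
      oracle <- oracle + resp$responses[b, i] * 1 * 1 * step
    }
    oracle <- oracle * 10 * 3
    expect_equal(unique(as.vector(cube$data[b, , ])), oracle,
                 tolerance = 1e-3)
  }
})

test_that("render is linear in exposure and dark-only without light", {
  bs <- load_band_table("cam4x4")
  resp <- make_sensor_responses(bs)
  scene <- make_uniform_scene(8, 8, reflectance = 0.5)
  base <- noiseless(acquisition_params(exposure_ms = 5,
                                       vignetting_strength = 0.3))
  dbl <- base; dbl$exposure_ms <- 10
  f1 <- render_mosaic_frame(scene, make_illumination("flat"), resp, base)
  f2 <- render_mosaic_frame(scene, make_illumination("flat"), resp, dbl)
  s1 <- f1$pixels - base$dark_offset_counts
  s2 <- f2$pixels - base$dark_offset_counts
  expect_equal(s2, 2 * s1, tolerance = 1e-12)

  off <- spectral_curve(working_grid(), rep(0, length(working_grid())))
  fd <- render_mosaic_frame(scene, off, resp, base)
  expect_true(all(fd$pixels == base$dark_offset_counts))
})

test_that("filter-wheel stack renders one frame per band, linear in reflectance", {
  bs <- load_band_table("filter_wheel")
  acq <- noiseless(acquisition_params(exposure_ms = 42,
                                      vignetting_strength = 0))
  g5 <- render_filterwheel_stack(make_uniform_scene(6, 6, 0.5), bs, acq)
  g10 <- render_filterwheel_stack(make_uniform_scene(6, 6, 1.0), bs, acq)
  expect_equal(dim(g5$frames)[1], 19L)
  for (b in seq_len(19)) {
    r <- mean(g5$frames[b, , ] - acq$dark_offset_counts) /
      mean(g10$frames[b, , ] - acq$dark_offset_counts)
    expect_equal(r, 0.5, tolerance = 1e-9)
  }

  # under LED illumination the 850 nm band signal is tiny vs the 540 nm band
  # (the LED's much higher flux requires a far shorter exposure)
  acq_led <- noiseless(acquisition_params(exposure_ms = 0.5,
                                          vignetting_strength = 0))
  led <- render_filterwheel_stack(make_uniform_scene(6, 6, 0.9), bs, acq_led,
                                  envelope = make_illumination("led"))
  s540 <- mean(led$frames[which(bs$center_nm == 540), , ]) -
    acq_led$dark_offset_counts
  s850 <- mean(led$frames[which(bs$center_nm == 850), , ]) -
    acq_led$dark_offset_counts
  expect_lt(s850, 0.05 * s540)
})

test_that("reference frames: dark statistics and white metadata", {
  bs <- load_band_table("cam4x4")
  resp <- make_sensor_responses(bs)
  acq <- acquisition_params(exposure_ms = 65, read_noise_sd_counts = 2,
                            shot_noise = FALSE, seed = 11)
  refs <- render_reference_frames(acq, make_illumination("xenon"), resp,
                                  n_dark = 100, shape = c(24, 24))
  stack <- simplify2array(refs$dark_frames)
  px_sd <- apply(stack, c(1, 2), sd)
  expect_equal(median(px_sd), 2, tolerance = 0.1)
  expect_equal(mean(stack), acq$dark_offset_counts, tolerance = 0.01)
  expect_equal(refs$white_exposure_ms, 65)

  # white frame with illumination off is indistinguishable from dark
  off <- spectral_curve(working_grid(), rep(0, length(working_grid())))
  refs_off <- render_reference_frames(noiseless(acq), off, resp,
                                      n_dark = 2, shape = c(24, 24))
  expect_equal(mean(refs_off$white$pixels), mean(refs_off$dark_frames[[1]]))
})

test_that("same seed gives bit-identical frames", {
  bs <- load_band_table("cam5x5")
  resp <- make_sensor_responses(bs, secondary_peaks = "default")
  scene <- make_chart_scene(make_reference_chart(3), tile_px = 5)
  acq <- acquisition_params(exposure_ms = 110, seed = 42)
  f1 <- render_mosaic_frame(scene, make_illumination("xenon"), resp, acq)
  f2 <- render_mosaic_frame(scene, make_illumination("xenon"), resp, acq)
  expect_identical(f1$pixels, f2$pixels)
  acq2 <- acq; acq2$seed <- 43
  f3 <- render_mosaic_frame(scene, make_illumination("xenon"), resp, acq2)
  expect_false(identical(f1$pixels, f3$pixels))
})
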