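# Synthetic-data generators: curvature waves, centerline reconstruction,
# mask rendering, coupled calcium traces and RFT bouts.

test_that("curvature wave follows the closed-form travelling sine", {
  # zero amplitude -> all-zero kymograph
  k0 <- make_curvature_wave(wave_params(curvature_amplitude = 0, duration = 2))
  expect_equal(unclass(k0), matrix(0, 10, 100), ignore_attr = TRUE)

  # closed-form evaluation at a segment midpoint: n = 10 puts segment 3 at
  # s = 0.25, so kappa(0.25, 0) = sin(-pi/2) = -1
  k <- make_curvature_wave(wave_params(curvature_amplitude = 1, frequency = 1,
                                       wavelength_fraction = 1, duration = 2,
                                       frame_rate = 5, n_segments = 10))
  expect_equal(nrow(k), 10L)
  expect_equal(unclass(k)[1, 3], sin(-pi / 2), tolerance = 1e-12)

  # posterior segments lag anterior ones: zero-crossing times shift by
  # (delta s / lambda) of a period
  p <- wave_params(curvature_amplitude = 1, wavelength_fraction = 0.65,
                   duration = 4, frame_rate = 50)
  kk <- unclass(make_curvature_wave(p))
  upcross <- function(v) {
    i <- which(v[-length(v)] < 0 & v[-1] >= 0)[2]
    i + (0 - v[i]) / (v[i + 1] - v[i])
  }
  dt_frames <- upcross(kk[, 20]) - upcross(kk[, 10])
  expect_equal(dt_frames / 50, 0.1 / 0.65, tolerance = 0.02)
})

test_that("invalid wave parameters raise configuration errors naming the field", {
  expect_error(wave_params(frequency = 0), "frequency")
  expect_error(wave_params(wavelength_fraction = 3), "wavelength_fraction")
  expect_error(wave_params(n_segments = 5), "n_segments")
  expect_error(wave_params(noise_sd = -1), "noise_sd")
})

test_that("centerline reconstruction inverts curvature", {
  # zero curvature -> straight segment of length L
  cl <- centerline_from_curvature(rep(0, 100), 1)
  expect_equal(attr(cl, "arclength"), 1)
  expect_equal(unclass(cl)[101, ], c(x = 1, y = 0), tolerance = 1e-12)

  # constant kappa*L = pi -> half circle, endpoint distance 2L/pi
  cl2 <- centerline_from_curvature(rep(pi, 100), 1)
  d <- sqrt(sum((unclass(cl2)[101, ] - unclass(cl2)[1, ])^2))
  expect_equal(d, 2 / pi, tolerance = 1e-3)

  # round trip: curvature -> centerline -> curvature within 1% of amplitude
  for (seed in 1:10) {
    set.seed(seed)
    A <- runif(1, 0.5, 2 * pi)
    lam <- runif(1, 0.4, 1.5)
    ph <- runif(1, 0, 2 * pi)
    kap <- A * sin(2 * pi * ((1:100 - 0.5) / 100) / lam + ph)
    rec <- compute_curvature(centerline_from_curvature(kap, 1))
    expect_lt(max(abs(rec - kap)), 0.01 * A)
  }
})

test_that("rendered masks are stadium-accurate, connected and inextensible", {
  cl <- centerline_from_curvature(rep(0, 100), 1, origin = c(0.5, 1.0))
  fr <- render_worm_mask(cl, width_profile = 0.04, image_shape = c(400, 400),
                         mm_per_px = 0.005)
  area <- sum(fr$mask) * 0.005^2
  expect_equal(area, 2 * 0.04 * 1 + pi * 0.04^2, tolerance = 0.05)

  expect_error(render_worm_mask(cl, width_profile = 0,
                                image_shape = c(400, 400),
                                mm_per_px = 0.005),
               "width profile")

  mv <- small_movie(duration = 2)
  areas <- vapply(mv$frames, function(f) sum(f$mask), 1)
  ncomp <- vapply(mv$frames, function(f)
    max(EBImage::bwlabel(EBImage::Image(t(f$mask)))), 1)
  expect_true(all(ncomp == 1))
  expect_lt(max(abs(areas - mean(areas))) / mean(areas), 0.05)

  # worm that does not fit raises a rendering error
  expect_error(render_worm_mask(cl, image_shape = c(100, 100),
                                mm_per_px = 0.005),
               "rendering error")
})

test_that("synthetic movies have the requested frame count and are seed-pure", {
  p <- wave_params(duration = 10, noise_sd = 0.1, seed = 9)
  mv1 <- make_synthetic_movie(p)
  mv2 <- make_synthetic_movie(p)
  expect_length(mv1$frames, 50L)
  expect_identical(mv1$ground_truth$kymograph, mv2$ground_truth$kymograph)
  expect_identical(mv1$frames[[17]]$mask, mv2$frames[[17]]$mask)
  # the generator restores the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(make_curvature_wave(p))
  expect_identical(before, .Random.seed)
})

test_that("calcium traces are rectified, lagged copies of head bending", {
  k <- make_curvature_wave(wave_params(duration = 30, seed = 3))

  # zero gain: traces are flat baseline, uncorrelated with bending
  ca0 <- make_calcium_traces(k, gain = 0, baseline = 7, noise_sd = 0.5,
                             seed = 2)
  expect_equal(mean(ca0$ventral$raw), 7, tolerance = 0.2)
  cg <- cross_correlate(head_curvature(k),
                        normalize_trace(ca0$ventral), max_lag = 5)
  expect_lt(max(abs(cg$coef), na.rm = TRUE), 0.35)

  # noise 0, lag 0: traces are exact rectified copies of head bending, so
  # the ventral trace peaks with ventral bending and the dorsal with dorsal
  ca <- make_calcium_traces(k, lag = 0, noise_sd = 0)
  kh <- head_curvature(k)$values
  expect_equal(ca$ventral$raw, 10 + pmax(kh, 0), tolerance = 1e-12)
  expect_equal(ca$dorsal$raw, 10 + pmax(-kh, 0), tolerance = 1e-12)

  expect_error(make_calcium_traces(k, lag = 1000), "lag")
})

test_that("RFT bout generator draws from the efficiency curve", {
  b <- make_rft_bouts(1.6, 50, c(5, 45), efficiency_noise_sd = 0, seed = 1)
  expect_equal(b$efficiency, rft_efficiency(b$theta_a, 1.6), tolerance = 1e-12)
  expect_identical(b, make_rft_bouts(1.6, 50, c(5, 45), 0, seed = 1))
  expect_error(make_rft_bouts(1, 50), "isotropic")
  expect_error(make_rft_bouts(1.6, 2), "n_bouts")
  # noisy efficiencies are truncated at zero
  bn <- make_rft_bouts(1.2, 500, c(1, 10), efficiency_noise_sd = 0.2, seed = 4)
  expect_true(all(bn$efficiency >= 0))
})
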