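# Locomotion kinematics: bout segmentation, speeds, angle of attack,
# binning and epoch comparisons.

test_that("bout segmentation respects exclusions and minimum duration", {
  k <- make_curvature_wave(wave_params(duration = 15, seed = 1))

  b <- segment_bouts(k, min_duration = 10)
  expect_identical(nrow(b), 1L)
  expect_identical(c(b$start, b$end), c(1L, 75L))

  # a 2 s flagged reversal in the middle splits the record in two
  flags <- rep(FALSE, 75); flags[36:45] <- TRUE
  b2 <- segment_bouts(k, min_duration = 5, reversal_flags = flags)
  expect_identical(nrow(b2), 2L)
  expect_true(all(b2$end[1] < 36, b2$start[2] > 45))

  # no qualifying bout: empty with a warning
  expect_warning(b3 <- segment_bouts(k, min_duration = 20), "no qualifying")
  expect_identical(nrow(b3), 0L)

  # property: bouts never overlap excluded frames (randomised insertions)
  set.seed(5)
  for (i in 1:30) {
    fl <- rep(FALSE, 75)
    fl[sample(75, sample(3:12, 1))] <- TRUE
    bb <- suppressWarnings(segment_bouts(k, min_duration = 2,
                                         reversal_flags = fl))
    if (nrow(bb) > 0)
      for (j in seq_len(nrow(bb)))
        expect_false(any(fl[bb$start[j]:bb$end[j]]))
  }

  # turn frames (|mean body curvature| above threshold) are excluded
  km <- unclass(k); km[20:24, ] <- km[20:24, ] + 2
  kt <- wormbend:::new_kymograph(km, 5, 1)
  bt <- segment_bouts(kt, min_duration = 2, turn_threshold = pi / 2)
  expect_false(any(vapply(seq_len(nrow(bt)), function(j)
    any(bt$start[j]:bt$end[j] %in% 20:24), TRUE)))
})

test_that("actual speed is the projected net displacement rate", {
  t <- seq(0, 10, by = 0.2)
  tr <- data.frame(time_s = t, x = 0.1 * t, y = 0)
  expect_equal(actual_speed(tr), 0.1, tolerance = 1e-12)

  # stationary undulation: zero
  tr0 <- data.frame(time_s = t, x = 0.02 * sin(2 * pi * t), y = 0)
  tr0$x[length(t)] <- tr0$x[1]
  expect_equal(actual_speed(tr0), 0, tolerance = 1e-12)

  expect_error(actual_speed(tr[1, , drop = FALSE]), "2 frames")
})

test_that("wave speed equals wavelength times frequency", {
  k <- make_curvature_wave(wave_params(curvature_amplitude = 3,
                                       wavelength_fraction = 1,
                                       duration = 30, seed = 1))
  expect_equal(as.numeric(wave_speed(k)), 1, tolerance = 0.03)

  k2 <- make_curvature_wave(wave_params(curvature_amplitude = 3,
                                        wavelength_fraction = 0.5,
                                        duration = 30, seed = 1))
  expect_equal(as.numeric(wave_speed(k2)), 0.5, tolerance = 0.03)

  # incoherent kymograph -> wave-speed error
  set.seed(8)
  wn <- wormbend:::new_kymograph(matrix(rnorm(150 * 100), 150, 100), 5, 1)
  expect_error(wave_speed(wn), "wave-speed error")

  # tail-to-head wave comes out negative
  kr <- wormbend:::new_kymograph(unclass(k)[, 100:1], 5, 1)
  expect_lt(as.numeric(wave_speed(kr)), 0)
})

test_that("angle of attack matches the mean-|sin| closed form and is linear", {
  # straight worm gliding along its own axis
  straight <- list(centerline_from_curvature(rep(0, 100), 1))
  expect_equal(angle_of_attack(straight, c(1, 0)), 0, tolerance = 1e-9)

  # psi = theta0 sin(...): mean |psi| = (2/pi) theta0 over >= 5 cycles
  times <- seq(0, 0.9, by = 0.1)
  for (th0 in c(8, 16)) {
    cls <- prescribed_psi_centerlines(th0 * pi / 180, lam = 0.2, times)
    expect_equal(angle_of_attack(cls, c(1, 0)), (2 / pi) * th0,
                 tolerance = 0.02 * (2 / pi) * th0 + 0.05)
  }
  # doubling the angle doubles theta_a within 3% (small angles)
  a1 <- angle_of_attack(prescribed_psi_centerlines(8 * pi / 180, 0.2, times),
                        c(1, 0))
  a2 <- angle_of_attack(prescribed_psi_centerlines(16 * pi / 180, 0.2, times),
                        c(1, 0))
  expect_equal(a2 / a1, 2, tolerance = 0.03)

  expect_error(angle_of_attack(straight, c(0, 0)), "undefined direction")
})

test_that("bout kinematics compose into efficiency = V_a / V_w <= 1", {
  p <- wave_params(duration = 12, seed = 5)
  mv <- make_synthetic_movie(p, image_shape = c(440, 440), drift = c(0.03, 0))
  kym <- build_kymograph(mv$frames)
  bouts <- segment_bouts(kym, attr(kym, "track"), min_duration = 10)
  bk <- bout_kinematics(kym, bouts)
  expect_identical(nrow(bk), 1L)
  expect_equal(bk$V_a, 0.03, tolerance = 0.05)
  expect_equal(bk$V_w, 0.65, tolerance = 0.02)
  expect_equal(bk$efficiency, bk$V_a / bk$V_w, tolerance = 1e-12)
  expect_lte(bk$efficiency, 1)
  expect_gt(bk$head_amplitude, 0)
})

test_that("kinematics are frame-rate invariant", {
  vals <- lapply(c(5, 10), function(fr) {
    p <- wave_params(duration = 12, frame_rate = fr, seed = 5)
    k <- make_curvature_wave(p)
    cls <- lapply(seq_len(nrow(k)), function(i)
      centerline_from_curvature(unclass(k)[i, ], 1))
    c(vw = as.numeric(wave_speed(k)),
      th = angle_of_attack(cls, c(1, 0)))
  })
  expect_equal(vals[[1]]["vw"], vals[[2]]["vw"], tolerance = 0.03)
  expect_equal(vals[[1]]["th"], vals[[2]]["th"], tolerance = 0.03)
})

test_that("angle binning reports means, SEMs and bout counts", {
  one <- data.frame(theta_a = 12, V_a = 0.1, V_w = 0.5)
  b1 <- bin_by_angle(one, 5)
  expect_identical(nrow(b1), 1L)
  expect_true(is.na(b1$V_a_sem))

  two <- data.frame(theta_a = c(11, 13), V_a = c(0.1, 0.3), V_w = c(0.5, 0.7))
  b2 <- bin_by_angle(two, 5)
  expect_equal(b2$V_a_mean, 0.2)
  expect_equal(b2$V_a_sem, 0.1)
  expect_identical(b2$n, 2L)

  # empty bins are omitted
  sparse <- data.frame(theta_a = c(2, 42), V_a = c(0.1, 0.2),
                       V_w = c(0.5, 0.5))
  expect_identical(nrow(bin_by_angle(sparse, 5)), 2L)
})

test_that("epoch fractional change has the expected sign and magnitude", {
  pre <- data.frame(V_a = c(0.2, 0.2), efficiency = c(0.1, 0.1))
  expect_equal(epoch_fractional_change(pre, pre, "V_a")$frac_change, 0)
  half <- pre; half$V_a <- half$V_a / 2
  expect_equal(epoch_fractional_change(pre, half, "V_a")$frac_change, -0.5)
  expect_error(epoch_fractional_change(pre[0, ], pre), "at least one bout")
  zero <- pre; zero$V_a <- 0
  expect_error(epoch_fractional_change(zero, pre, "V_a"), "zero pre-epoch")

  # end-to-end: "stimulation" halving the angle of attack reduces V_a in
  # the median trial (>= 20 trials)
  vwfun <- function(th) 0.6 * (1 - 0.005 * th)
  pre_b <- make_rft_bouts(1.6, 60, c(30, 45), 0.02, seed = 1,
                          wave_speed_fun = vwfun)
  dur_b <- make_rft_bouts(1.6, 60, c(15, 22.5), 0.02, seed = 2,
                          wave_speed_fun = vwfun)
  pre_b$trial <- rep(1:20, 3)
  dur_b$trial <- rep(1:20, 3)
  fc <- epoch_fractional_change(pre_b, dur_b, "V_a")
  expect_identical(nrow(fc), 20L)
  expect_lt(median(fc$frac_change), 0)
})
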