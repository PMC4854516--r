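# Posture module: binarisation, endpoint detection, centerline extraction,
# curvature and kymograph assembly.

test_that("binarisation keeps the worm and rejects degenerate images", {
  mv <- small_movie()
  m <- mv$frames[[2]]$mask

  # fixed threshold on an already-binary image is idempotent
  wf <- binarize_frame(m * 1.0, method = "fixed", threshold = 0.5,
                       mm_per_px = 0.005)
  expect_identical(wf$mask, m)

  expect_error(binarize_frame(matrix(0, 50, 50)), "segmentation error")

  # Gaussian pixel noise at 10% of the dynamic range: Jaccard >= 0.95
  set.seed(1)
  noisy <- m + matrix(rnorm(length(m), 0, 0.1), nrow(m))
  rec <- binarize_frame(noisy, method = "otsu", mm_per_px = 0.005)
  jac <- sum(rec$mask & m) / sum(rec$mask | m)
  expect_gte(jac, 0.95)

  # a speckle component away from the worm is discarded
  speck <- m; speck[5:7, 5:7] <- TRUE
  rec2 <- binarize_frame(speck * 1.0, method = "fixed", threshold = 0.5,
                         mm_per_px = 0.005)
  expect_identical(rec2$mask, m)
})

test_that("endpoints sit at the body tips, not at bend apices", {
  # straight stadium-shaped worm: endpoints within 2 px of the cap tips
  cl <- centerline_from_curvature(rep(0, 100), 1, origin = c(0.5, 1.0))
  fr <- render_worm_mask(cl, width_profile = 0.04, image_shape = c(400, 400),
                         mm_per_px = 0.005)
  ep <- find_endpoints(fr)
  # the rendered caps reach half a body-width beyond the centerline ends
  tips <- rbind(c(0.5 - 0.04, 1.0), c(1.5 + 0.04, 1.0))
  d <- pmin(sqrt(colSums((t(ep) - tips[1, ])^2)),
            sqrt(colSums((t(ep) - tips[2, ])^2)))
  expect_lt(max(d) / 0.005, 2)

  # a disc has no convex-curvature extrema
  disc <- matrix(FALSE, 101, 101)
  xg <- row(disc) - 51; yg <- col(disc) - 51
  disc[xg^2 + yg^2 <= 30^2] <- TRUE
  expect_error(find_endpoints(wormbend:::new_worm_frame(disc, 0, 0.005)),
               "endpoint-detection error")

  # U-shaped worm (half-circle centerline): endpoints at the tips,
  # not at the outer apex of the bend
  clu <- centerline_from_curvature(rep(pi, 100), 1, origin = c(0.9, 1.2))
  fru <- render_worm_mask(clu, image_shape = c(400, 400), mm_per_px = 0.005)
  epu <- find_endpoints(fru)
  tipsu <- unclass(clu)[c(1, 101), ]
  du <- pmin(sqrt(colSums((t(epu) - tipsu[1, ])^2)),
             sqrt(colSums((t(epu) - tipsu[2, ])^2)))
  expect_lt(max(du) / 0.005, 4)
})

test_that("head assignment follows the wave-propagation direction", {
  # noisy kymographs over 100 seeds: head correctly at index 0 in >= 95
  ok <- 0L
  for (s in 1:100) {
    k <- make_curvature_wave(wave_params(duration = 6, noise_sd = 0.4,
                                         seed = s))
    r <- tryCatch(assign_head_tail(k), error = function(e) NULL)
    if (!is.null(r) && r$head_end == "first") ok <- ok + 1L
  }
  expect_gte(ok, 95L)

  # time reversal flips the assignment
  k <- make_curvature_wave(wave_params(duration = 20, seed = 3))
  kr <- wormbend:::new_kymograph(unclass(k)[rev(seq_len(nrow(k))), ], 5, 1)
  expect_identical(assign_head_tail(k)$head_end, "first")
  expect_identical(assign_head_tail(kr)$head_end, "last")

  # static worm: no phase gradient
  ks <- wormbend:::new_kymograph(matrix(1, 50, 100), 5, 1)
  expect_error(assign_head_tail(ks), "orientation error")
  # manual override is honoured without looking at the data
  expect_identical(assign_head_tail(ks, override = "last")$head_end, "last")
})

test_that("centerline extraction is accurate and rigid-motion equivariant", {
  # straight worm: centerline collinear with the axis within 1 px
  cl <- centerline_from_curvature(rep(0, 100), 1, origin = c(0.5, 1.0))
  fr <- render_worm_mask(cl, width_profile = 0.04, image_shape = c(400, 400),
                         mm_per_px = 0.005)
  ep <- find_endpoints(fr)
  rec <- extract_centerline(fr, ep[1, ], ep[2, ], endpoints = ep)
  expect_lt(max(abs(unclass(rec)[, 2] - 1.0)) / 0.005, 1)

  # rigid rotation by 37 degrees: curvature unchanged, arclength within 1%
  kap <- 3 * sin(2 * pi * ((1:100 - 0.5) / 100) / 0.65)
  extract_one <- function(psi0, origin) {
    cl <- centerline_from_curvature(kap, 1, psi0 = psi0, origin = origin)
    sh <- c(0.8, 0.8) - colMeans(unclass(cl)[, 1:2])
    cl <- wormbend:::new_centerline(sweep(unclass(cl)[, 1:2], 2, sh, "+"), 1)
    fr <- render_worm_mask(cl, image_shape = c(320, 320), mm_per_px = 0.005)
    ep <- find_endpoints(fr)
    hd <- ep[which.min(colSums((t(ep) - unclass(cl)[1, ])^2)), ]
    rc <- extract_centerline(fr, hd, ep[ep[, 1] != hd[1], ], endpoints = ep)
    list(k = compute_curvature(rc), len = attr(rc, "arclength"))
  }
  a <- extract_one(0, c(0, 0))
  b <- extract_one(37 * pi / 180, c(0, 0))
  # interior segments: the rotated raster is pixelated differently, so the
  # difference carries two independent single-frame discretisation noise
  # realisations (~10% each); rotation must add no systematic gain change
  expect_lt(sqrt(mean((a$k - b$k)[11:90]^2)) / sqrt(mean(kap^2)), 0.2)
  expect_equal(unname(coef(lm(b$k[11:90] ~ a$k[11:90]))[2]), 1,
               tolerance = 0.05)
  expect_lt(abs(a$len - b$len) / a$len, 0.01)

  # half-circle worm: recovered arclength within 2% of L
  clu <- centerline_from_curvature(rep(pi, 100), 1, origin = c(0.9, 1.2))
  fru <- render_worm_mask(clu, image_shape = c(400, 400), mm_per_px = 0.005)
  epu <- find_endpoints(fru)
  rcu <- extract_centerline(fru, epu[1, ], epu[2, ], endpoints = epu)
  expect_lt(abs(attr(rcu, "arclength") - 1), 0.02)
})

test_that("curvature computation matches closed forms and flips under mirror", {
  straight <- centerline_from_curvature(rep(0, 100), 1)
  expect_equal(compute_curvature(straight), rep(0, 100), tolerance = 1e-12)

  # circular arc of radius R with L = pi R: kappa * L = pi everywhere
  arc <- centerline_from_curvature(rep(pi, 100), 1)
  expect_equal(compute_curvature(arc), rep(pi, 100), tolerance = 0.02 * pi)

  # mirror across the x axis negates curvature exactly
  kap <- 3 * sin(2 * pi * ((1:100 - 0.5) / 100) / 0.65)
  cl <- centerline_from_curvature(kap, 1)
  mir <- unclass(cl); mir[, 2] <- -mir[, 2]
  expect_equal(compute_curvature(wormbend:::new_centerline(mir, 1)),
               -compute_curvature(cl), tolerance = 1e-12)

  # ventral_sign flag flips the sign convention
  expect_equal(compute_curvature(cl, ventral_sign = -1),
               -compute_curvature(cl), tolerance = 1e-12)

  # single rendered frame: per-segment curvature within 5% RMSE of truth
  mv <- small_movie(duration = 2)
  gt <- mv$ground_truth
  fr <- mv$frames[[4]]
  ep <- find_endpoints(fr)
  hd <- ep[which.min(colSums((t(ep) - unclass(gt$centerlines[[4]])[1, ])^2)), ]
  rc <- extract_centerline(fr, hd, ep[ep[, 1] != hd[1], ], endpoints = ep)
  k <- compute_curvature(rc)
  tru <- unclass(gt$kymograph)[4, ]
  # single-frame extraction noise: interior segments within 8% of the wave
  # amplitude, all segments within 12% (the tip segments are the least
  # reliable part of any mask-based centerline); the movie-level closure
  # bound lives in the acceptance suite
  expect_lt(sqrt(mean((k - tru)[6:95]^2)), 0.08 * max(abs(tru)))
  expect_lt(sqrt(mean((k - tru)^2)), 0.12 * max(abs(tru)))
})

test_that("kymograph assembly records failures, lengths and orientation", {
  mv <- small_movie(duration = 10)
  frames <- mv$frames
  # corrupt one frame into a disc: posture extraction fails, row is missing
  disc <- matrix(FALSE, 320, 320)
  disc[(row(disc) - 160)^2 + (col(disc) - 160)^2 <= 40^2] <- TRUE
  frames[[7]]$mask <- disc
  kym <- build_kymograph(frames)
  expect_identical(dim(unclass(kym)), c(50L, 100L))
  expect_identical(attr(kym, "failed_frames"), 7L)
  expect_true(all(is.na(unclass(kym)[7, ])))
  expect_false(anyNA(unclass(kym)[-7, ]))

  # per-frame arclength varies < 3% (inextensible body)
  lens <- attr(kym, "frame_lengths")
  expect_lt(stats::sd(lens, na.rm = TRUE) / mean(lens, na.rm = TRUE), 0.03)

  # too many corrupted frames -> quality error
  bad <- mv$frames
  for (i in 1:20) bad[[i]]$mask <- disc
  expect_error(build_kymograph(bad), "quality error")

  # translation equivariance: a rigidly shifted movie gives the same rows
  shifted <- lapply(mv$frames, function(f) {
    m2 <- matrix(FALSE, 320, 320)
    m2[11:320, 1:300] <- f$mask[1:310, 21:320]
    f$mask <- m2; f
  })
  k1 <- build_kymograph(mv$frames)
  k2 <- build_kymograph(shifted)
  expect_lt(sqrt(mean((unclass(k1) - unclass(k2))^2, na.rm = TRUE)) /
              sqrt(mean(unclass(k1)^2, na.rm = TRUE)), 0.02)
})
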