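# Synthetic worm data: curvature waves, rendered movies, coupled calcium
# traces and RFT locomotion bouts with known ground truth.

#' Parameters of a synthetic dorsoventral curvature wave
#'
#' Bundles the parameters of a posteriorly travelling sinusoidal bending wave,
#' the standard kinematic model of C. elegans forward undulation. Curvature is
#' stored body-length-normalised (dimensionless kappa*L), positive = ventral
#' bending. Defaults describe an adult worm undulating at 1 Hz with roughly
#' two-thirds of a wavelength per body length, recorded at 5 Hz.
#'
#' @param curvature_amplitude peak kappa*L of the wave (dimensionless).
#' @param wavelength_fraction spatial period as a fraction of body length,
#'   in (0, 2].
#' @param frequency temporal frequency in Hz.
#' @param duration recording duration in seconds.
#' @param frame_rate sampling rate in Hz.
#' @param n_segments number of body segments (columns of the kymograph).
#' @param body_length worm length in mm.
#' @param noise_sd additive Gaussian noise on kappa*L per segment and frame.
#' @param seed integer seed; generators are pure functions of it.
#' @return an object of class \code{wave_params}.
#' @export
wave_params <- function(curvature_amplitude = 4, wavelength_fraction = 0.65,
                        frequency = 1, duration = 30, frame_rate = 5,
                        n_segments = 100, body_length = 1, noise_sd = 0,
                        seed = 1L) {
  check_positive(frequency, "frequency")
  check_positive(frame_rate, "frame_rate")
  check_positive(duration, "duration")
  check_positive(body_length, "body_length")
  if (!is.numeric(wavelength_fraction) || wavelength_fraction <= 0 ||
      wavelength_fraction > 2)
    stop_config("wavelength_fraction", "must lie in (0, 2]")
  if (!is.numeric(n_segments) || n_segments < 10)
    stop_config("n_segments", "must be at least 10")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_config("noise_sd", "must be non-negative")
  if (!is.numeric(curvature_amplitude) || !is.finite(curvature_amplitude) ||
      curvature_amplitude < 0)
    stop_config("curvature_amplitude", "must be finite and non-negative")
  structure(list(curvature_amplitude = curvature_amplitude,
                 wavelength_fraction = wavelength_fraction,
                 frequency = frequency, duration = duration,
                 frame_rate = frame_rate, n_segments = as.integer(n_segments),
                 body_length = body_length, noise_sd = noise_sd,
                 seed = seed),
            class = "wave_params")
}

new_kymograph <- function(values, frame_rate, body_length,
                          frame_lengths = NULL) {
  structure(values, frame_rate = frame_rate, body_length = body_length,
            frame_lengths = frame_lengths, class = "curvature_kymograph")
}

#' @export
print.curvature_kymograph <- function(x, ...) {
  cat(sprintf("curvature kymograph: %d frames x %d segments, %.3g Hz, L = %.3g mm\n",
              nrow(x), ncol(x), attr(x, "frame_rate"), attr(x, "body_length")))
  cat(sprintf("  kappa*L range: [%.3g, %.3g], %d missing frames\n",
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE)),
              sum(!stats::complete.cases(unclass(x)))))
  invisible(x)
}

#' Generate a travelling curvature wave kymograph
#'
#' Builds kappa*L(s, t) = A sin(2 pi f t - 2 pi s / lambda) + noise at segment
#' midpoints s = (i - 1/2)/n, i = 1..n. The phase velocity is positive
#' head-to-tail, as in forward locomotion.
#'
#' @param params a \code{\link{wave_params}} object.
#' @return a \code{curvature_kymograph}: frames x segments matrix of kappa*L
#'   with attributes \code{frame_rate} and \code{body_length}.
#' @export
make_curvature_wave <- function(params) {
  stopifnot(inherits(params, "wave_params"))
  p <- params
  n_frames <- max(1L, round(p$duration * p$frame_rate))
  tt <- (seq_len(n_frames) - 1L) / p$frame_rate
  s <- (seq_len(p$n_segments) - 0.5) / p$n_segments
  k <- outer(tt, s, function(t, s)
    p$curvature_amplitude * sin(2 * pi * p$frequency * t -
                                2 * pi * s / p$wavelength_fraction))
  if (p$noise_sd > 0)
    k <- k + with_seed(p$seed,
                       matrix(stats::rnorm(length(k), 0, p$noise_sd),
                              nrow(k), ncol(k)))
  new_kymograph(k, p$frame_rate, p$body_length)
}

new_centerline <- function(points, arclength, frame_index = NA_integer_) {
  structure(points, arclength = arclength, frame_index = frame_index,
            class = "centerline")
}

#' Reconstruct a centerline from one kymograph row
#'
#' Integrates the tangent angle psi(s) = psi0 + integral of kappa ds and then
#' the positions; the inverse of \code{\link{compute_curvature}}. Head at
#' index 0 (row 1).
#'
#' @param curvature_row vector of n dimensionless curvatures kappa*L at
#'   segment midpoints.
#' @param body_length worm length L in mm.
#' @param psi0 heading of the first segment in radians.
#' @param origin head-tip position, length-2 numeric (mm).
#' @return a \code{centerline}: (n+1) x 2 matrix of (x, y) positions in mm
#'   with uniform spacing and total arclength \code{body_length}.
#' @export
centerline_from_curvature <- function(curvature_row, body_length,
                                      psi0 = 0, origin = c(0, 0)) {
  k <- as.numeric(curvature_row)
  if (any(!is.finite(k))) stop("curvature values must be finite")
  n <- length(k)
  ds <- body_length / n
  kappa <- k / body_length            # physical curvature 1/mm
  # tangent angle at segment midpoints via cumulative trapezoid from s = 0
  psi <- psi0 + ds * (cumsum(kappa) - kappa / 2)
  x <- origin[1] + c(0, cumsum(ds * cos(psi)))
  y <- origin[2] + c(0, cumsum(ds * sin(psi)))
  new_centerline(cbind(x = x, y = y), arclength = body_length)
}

#' Default half-width profile of a synthetic worm
#'
#' Square-root-sine taper: widest mid-length, pointed at both tips (giving
#' the boundary its two convex-curvature extrema) but steep enough near the
#' ends that the rendered tip reaches within ~0.5\% of the true tip on a
#' pixel grid.
#'
#' @param s arclength positions in [0, 1].
#' @param body_length worm length in mm.
#' @param width_scale maximum half-width as a fraction of body length.
#' @return half-widths in mm.
#' @export
default_width_profile <- function(s, body_length = 1, width_scale = 0.04) {
  width_scale * body_length * sqrt(sin(pi * pmin(pmax(s, 0), 1)))
}

#' Render a worm mask from a centerline
#'
#' Paints the union of discs of local half-width centred on the centerline
#' points into a binary image. Pixel (1, 1) is the top-left; physical x runs
#' along columns and y upward along decreasing rows.
#'
#' @param centerline a \code{centerline} ((n+1) x 2 mm coordinates).
#' @param width_profile vector of half-widths in mm (recycled to the number of
#'   centerline points), or a function of arclength fraction s.
#' @param image_shape c(rows, cols) in pixels.
#' @param mm_per_px pixel size.
#' @return a \code{worm_frame}: list(mask, timestamp, mm_per_px).
#' @export
render_worm_mask <- function(centerline, width_profile = default_width_profile,
                             image_shape = c(160, 160), mm_per_px = 0.01) {
  pts <- unclass(centerline)[, 1:2, drop = FALSE]
  np <- nrow(pts)
  s <- seq(0, 1, length.out = np)
  w <- if (is.function(width_profile)) width_profile(s) else
    rep_len(width_profile, np)
  if (all(w <= 0)) stop("rendering error: width profile is identically zero")
  nr <- image_shape[1]; nc <- image_shape[2]
  cols <- pts[, 1] / mm_per_px + 0.5
  rows <- nr - pts[, 2] / mm_per_px + 0.5
  wpx <- w / mm_per_px
  margin <- 5
  if (any(cols - wpx < margin) || any(cols + wpx > nc - margin + 1) ||
      any(rows - wpx < margin) || any(rows + wpx > nr - margin + 1))
    stop("rendering error: worm does not fit inside the image with a 5 px margin")
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(np)) {
    if (wpx[i] <= 0) next
    r0 <- max(1L, floor(rows[i] - wpx[i])); r1 <- min(nr, ceiling(rows[i] + wpx[i]))
    c0 <- max(1L, floor(cols[i] - wpx[i])); c1 <- min(nc, ceiling(cols[i] + wpx[i]))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - rows[i])^2, (cc - cols[i])^2, "+")
    mask[rr, cc] <- mask[rr, cc] | (d2 <= wpx[i]^2)
  }
  if (!any(mask)) stop("rendering error: empty mask")
  new_worm_frame(mask, timestamp = 0, mm_per_px = mm_per_px)
}

new_worm_frame <- function(mask, timestamp, mm_per_px) {
  structure(list(mask = mask, timestamp = timestamp, mm_per_px = mm_per_px),
            class = "worm_frame")
}

#' Generate a synthetic single-worm movie with ground truth
#'
#' Composes \code{\link{make_curvature_wave}},
#' \code{\link{centerline_from_curvature}} and \code{\link{render_worm_mask}}
#' frame by frame. Each frame's centerline is centred in the image (emulating
#' a tracking stage) plus an optional rigid drift.
#'
#' @param params a \code{\link{wave_params}} object.
#' @param image_shape c(rows, cols) pixels.
#' @param mm_per_px pixel size.
#' @param width_scale maximum half-width as fraction of body length.
#' @param drift rigid translation velocity c(vx, vy) in mm/s.
#' @return list with \code{frames} (list of \code{worm_frame}) and
#'   \code{ground_truth} (kymograph, centerlines in image coordinates,
#'   head_index = 0, centroid track, params).
#' @export
make_synthetic_movie <- function(params, image_shape = c(320, 320),
                                 mm_per_px = 0.005, width_scale = 0.04,
                                 drift = c(0, 0)) {
  kym <- make_curvature_wave(params)
  n_frames <- nrow(kym)
  tt <- (seq_len(n_frames) - 1L) / params$frame_rate
  centre <- c(image_shape[2], image_shape[1]) * mm_per_px / 2
  wp <- function(s) default_width_profile(s, params$body_length, width_scale)
  frames <- vector("list", n_frames)
  cls <- vector("list", n_frames)
  track <- matrix(NA_real_, n_frames, 2)
  for (i in seq_len(n_frames)) {
    cl <- centerline_from_curvature(kym[i, ], params$body_length)
    shift <- centre - colMeans(unclass(cl)[, 1:2]) + drift * tt[i]
    pts <- sweep(unclass(cl)[, 1:2], 2, shift, "+")
    cl2 <- new_centerline(cbind(x = pts[, 1], y = pts[, 2]),
                          arclength = attr(cl, "arclength"), frame_index = i)
    fr <- render_worm_mask(cl2, wp, image_shape, mm_per_px)
    fr$timestamp <- tt[i]
    frames[[i]] <- fr
    cls[[i]] <- cl2
    track[i, ] <- colMeans(pts)
  }
  list(frames = frames,
       ground_truth = list(kymograph = kym, centerlines = cls,
                           head_index = 0L,
                           track = data.frame(time_s = tt, x = track[, 1],
                                              y = track[, 2]),
                           params = params))
}

#' Generate bending-locked synthetic calcium traces
#'
#' Emulates the anti-correlated ventral/dorsal head-motor-neuron GCaMP signals:
#' each trace is a half-wave-rectified copy of the (lagged) head curvature,
#' since the ventral and dorsal neurons respond to opposite bending directions.
#' Ventral bending is positive.
#'
#' @param kymograph a \code{curvature_kymograph}.
#' @param lag response delay in seconds (>= 0, rounded to whole frames).
#' @param gain fluorescence change per unit kappa*L (a.u.).
#' @param baseline resting fluorescence (a.u.).
#' @param noise_sd additive Gaussian noise (a.u.).
#' @param seed integer seed.
#' @param n_head number of anterior segments averaged into head curvature.
#' @return list(ventral, dorsal) of \code{\link{fluorescence_trace}} objects.
#' @export
make_calcium_traces <- function(kymograph, lag = 0, gain = 1, baseline = 10,
                                noise_sd = 0, seed = 1L, n_head = 18L) {
  fr <- attr(kymograph, "frame_rate")
  if (lag < 0) stop("lag must be non-negative")
  n <- nrow(kymograph)
  shift <- round(lag * fr)
  if (shift >= n) stop("lag exceeds trace duration")
  kh <- rowMeans(unclass(kymograph)[, seq_len(min(n_head, ncol(kymograph))),
                                    drop = FALSE])
  lagged <- if (shift > 0) c(rep(kh[1], shift), kh[seq_len(n - shift)]) else kh
  eps <- if (noise_sd > 0)
    with_seed(seed, matrix(stats::rnorm(2L * n, 0, noise_sd), n, 2)) else
    matrix(0, n, 2)
  ventral <- baseline + gain * pmax(lagged, 0) + eps[, 1]
  dorsal  <- baseline + gain * pmax(-lagged, 0) + eps[, 2]
  list(ventral = fluorescence_trace(ventral, frame_rate = fr),
       dorsal  = fluorescence_trace(dorsal, frame_rate = fr))
}

#' Generate synthetic RFT locomotion bouts
#'
#' Draws (angle of attack, efficiency) pairs from the small-angle
#' resistive-force-theory curve at a known drag ratio, with truncated Gaussian
#' observation noise on efficiency. Optionally attaches wave and actual speeds
#' via a user wave-speed model, so binned-speed analyses can be exercised.
#'
#' @param K_true ground-truth drag ratio C_perp/C_par (> 1).
#' @param n_bouts number of bouts (>= 3).
#' @param theta_range degrees, c(lo, hi) of the uniform angle-of-attack draw.
#' @param efficiency_noise_sd Gaussian sd added to efficiency, truncated at 0.
#' @param seed integer seed.
#' @param wave_speed_fun optional function theta_deg -> V_w (mm/s); when given,
#'   columns V_w and V_a = efficiency * V_w are added.
#' @return data.frame with columns theta_a (degrees) and efficiency.
#' @export
make_rft_bouts <- function(K_true, n_bouts = 100, theta_range = c(5, 45),
                           efficiency_noise_sd = 0.05, seed = 1L,
                           wave_speed_fun = NULL) {
  if (K_true <= 1)
    stop("no propulsion under isotropic drag: K_true must exceed 1")
  if (n_bouts < 3) stop("n_bouts must be at least 3")
  with_seed(seed, {
    theta <- stats::runif(n_bouts, theta_range[1], theta_range[2])
    eff <- rft_efficiency(theta, K_true)
    if (efficiency_noise_sd > 0)
      eff <- pmax(eff + stats::rnorm(n_bouts, 0, efficiency_noise_sd), 0)
    out <- data.frame(theta_a = theta, efficiency = eff)
    if (!is.null(wave_speed_fun)) {
      out$V_w <- wave_speed_fun(theta)
      out$V_a <- out$efficiency * out$V_w
    }
    out
  })
}
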