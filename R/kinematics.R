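# Bout segmentation and kinematics: actual speed, undulation wave speed,
# angle of attack, binned speeds and epoch comparisons.

#' Segment forward-locomotion bouts
#'
#' Returns maximal contiguous runs of forward frames of at least
#' \code{min_duration} seconds. A frame is excluded when it is flagged as a
#' reversal, when the posture failed extraction (missing kymograph row), or
#' when the worm is turning (|mean whole-body kappa*L| above
#' \code{turn_threshold}).
#'
#' @param kymograph a \code{curvature_kymograph}.
#' @param track centroid track data.frame(time_s, x, y) on the same time base.
#' @param min_duration seconds (bouts of forward locomotion are typically
#'   10-15 s).
#' @param reversal_flags optional logical vector marking reversal frames.
#' @param turn_threshold dimensionless |mean kappa*L| marking a turn frame.
#' @return data.frame(start, end) of frame indices; zero rows (with a
#'   warning) when no bout qualifies.
#' @export
segment_bouts <- function(kymograph, track = NULL, min_duration = 10,
                          reversal_flags = NULL, turn_threshold = pi / 2) {
  mat <- unclass(kymograph)
  fr <- attr(kymograph, "frame_rate")
  nf <- nrow(mat)
  if (!is.null(track) && nrow(track) != nf)
    stop("track and kymograph do not share a time base")
  ok <- stats::complete.cases(mat)
  mean_k <- rowMeans(mat)
  ok <- ok & is.finite(mean_k) & abs(mean_k) <= turn_threshold
  if (!is.null(reversal_flags)) ok <- ok & !reversal_flags
  min_frames <- ceiling(min_duration * fr)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  if (!any(keep)) {
    warning("no qualifying forward bout")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = starts[keep], end = ends[keep])
}

#' Actual forward speed of a bout
#'
#' Net centroid displacement over the bout, projected on the bout's mean
#' direction of motion (the unit vector of the net displacement itself),
#' divided by the bout duration.
#'
#' @param track data.frame(time_s, x, y), already restricted to the bout.
#' @return V_a in mm/s.
#' @export
actual_speed <- function(track) {
  if (nrow(track) < 2) stop("bout must span at least 2 frames")
  disp <- c(track$x[nrow(track)] - track$x[1], track$y[nrow(track)] - track$y[1])
  dur <- track$time_s[nrow(track)] - track$time_s[1]
  if (dur <= 0) stop("bout has zero duration")
  sqrt(sum(disp^2)) / dur
}

#' Undulation wave speed from the curvature kymograph
#'
#' Estimates the head-to-tail phase speed of the bending wave: the phase-lag
#' slope of the kymograph's dominant oscillation across interior segments
#' (segments 20-80 of 100 by default, avoiding head and tail edge noise) gives
#' the wavelength; the interpolated dominant frequency gives the period. This
#' phase-lag slope is the lag at which pairwise segment cross-correlations
#' peak, measured with sub-frame resolution.
#'
#' @param kymograph a \code{curvature_kymograph}, restricted to one bout.
#' @param body_length mm; taken from the kymograph when missing.
#' @param seg_range columns used for the phase fit.
#' @param min_r2 minimum R^2 of the phase-lag fit.
#' @param min_concentration minimum fraction of spectral power at the
#'   dominant frequency (rejects incoherent, noise-like kymographs).
#' @return V_w in mm/s, positive for a head-to-tail wave. The wavelength
#'   (body lengths) and frequency (Hz) are attached as attributes.
#' @export
wave_speed <- function(kymograph, body_length = NULL, seg_range = NULL,
                       min_r2 = 0.8, min_concentration = 0.2) {
  L <- body_length %||% attr(kymograph, "body_length")
  ps <- phase_slope(kymograph, seg_range)
  if (ps$concentration < min_concentration || ps$r2 < min_r2)
    stop("wave-speed error: no coherent travelling wave in the kymograph")
  n <- ps$n_segments_total
  wavelength <- 2 * pi / (abs(ps$slope) * n)     # body lengths
  if (nrow(kymograph) / attr(kymograph, "frame_rate") * ps$frequency < 2)
    stop("wave-speed error: fewer than 2 undulation cycles in the bout")
  vw <- sign(-ps$slope) * wavelength * ps$frequency * L
  structure(vw, wavelength = wavelength, frequency = ps$frequency,
            r2 = ps$r2)
}

#' Angle of attack of a bout
#'
#' Mean over frames and segments of the absolute acute angle between each
#' body segment's tangent and the bout's direction of forward movement.
#' Angles are unsigned and lie in [0, 90) degrees, as in the efficiency
#' theory.
#'
#' @param centerlines list of \code{centerline} objects for the bout frames.
#' @param direction length-2 vector: the bout's mean direction of motion
#'   (e.g. the net centroid displacement); need not be normalised.
#' @param trim optional c(lo, hi) fraction of body to include (default all).
#' @return theta_a in degrees.
#' @export
angle_of_attack <- function(centerlines, direction, trim = NULL) {
  nd <- sqrt(sum(direction^2))
  if (!is.finite(nd) || nd <= 0)
    stop("undefined direction of motion (zero net displacement)")
  d <- direction / nd
  angs <- unlist(lapply(centerlines, function(cl) {
    seg <- diff(unclass(cl)[, 1:2, drop = FALSE])
    if (!is.null(trim)) {
      n <- nrow(seg)
      keep <- max(1L, ceiling(trim[1] * n)):min(n, floor(trim[2] * n))
      seg <- seg[keep, , drop = FALSE]
    }
    len <- sqrt(rowSums(seg^2))
    cosang <- abs((seg[, 1] * d[1] + seg[, 2] * d[2]) / pmax(len, 1e-12))
    acos(pmin(cosang, 1))
  }))
  mean(angs) * 180 / pi
}

#' Per-bout kinematics table
#'
#' Computes V_a, V_w, angle of attack, efficiency V_a/V_w and head-bending
#' amplitude for each bout of a tracked movie, reconstructing per-frame
#' centerlines from the kymograph rows for the angle computation.
#'
#' @param kymograph a \code{curvature_kymograph} carrying a \code{track}
#'   attribute (as from \code{\link{build_kymograph}}), or supply
#'   \code{track} explicitly.
#' @param bouts data.frame(start, end) from \code{\link{segment_bouts}}.
#' @param track centroid track data.frame(time_s, x, y).
#' @return data.frame(t_start, t_end, V_a, V_w, theta_a, efficiency,
#'   head_amplitude), one row per bout that yielded a coherent wave.
#' @export
bout_kinematics <- function(kymograph, bouts, track = NULL) {
  track <- track %||% attr(kymograph, "track")
  if (is.null(track)) stop("a centroid track is required")
  fr <- attr(kymograph, "frame_rate")
  L <- attr(kymograph, "body_length")
  out <- lapply(seq_len(nrow(bouts)), function(i) {
    idx <- bouts$start[i]:bouts$end[i]
    tr <- track[idx, , drop = FALSE]
    sub <- new_kymograph(unclass(kymograph)[idx, , drop = FALSE], fr, L)
    vw <- tryCatch(as.numeric(wave_speed(sub)), error = function(e) NA_real_)
    if (!is.finite(vw) || vw <= 0) return(NULL)
    va <- actual_speed(tr)
    disp <- c(tr$x[nrow(tr)] - tr$x[1], tr$y[nrow(tr)] - tr$y[1])
    cls <- lapply(idx, function(j)
      centerline_from_curvature(unclass(kymograph)[j, ], L))
    th <- angle_of_attack(cls, disp)
    amp <- pop_sd(rowMeans(unclass(sub)[, seq_len(min(18L, ncol(sub))),
                                        drop = FALSE]))
    data.frame(t_start = track$time_s[idx[1]], t_end = track$time_s[idx[length(idx)]],
               V_a = va, V_w = vw, theta_a = th, efficiency = va / vw,
               head_amplitude = amp)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE))) %||%
    data.frame(t_start = numeric(0), t_end = numeric(0), V_a = numeric(0),
               V_w = numeric(0), theta_a = numeric(0), efficiency = numeric(0),
               head_amplitude = numeric(0))
}

#' Bin bout speeds by angle of attack
#'
#' Arithmetic mean and standard error of V_a and V_w per angle bin; empty
#' bins are omitted and the SEM of a single bout is reported as missing.
#'
#' @param bouts data.frame with columns theta_a, V_a, V_w.
#' @param bin_width degrees.
#' @return data.frame(bin_center, n, V_a_mean, V_a_sem, V_w_mean, V_w_sem).
#' @export
bin_by_angle <- function(bouts, bin_width = 5) {
  b <- floor(bouts$theta_a / bin_width)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  agg <- lapply(split(bouts, b), function(d)
    data.frame(bin_center = (floor(d$theta_a[1] / bin_width) + 0.5) * bin_width,
               n = nrow(d),
               V_a_mean = mean(d$V_a), V_a_sem = sem(d$V_a),
               V_w_mean = mean(d$V_w), V_w_sem = sem(d$V_w)))
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out[order(out$bin_center), , drop = FALSE]
}

#' Fractional change of a bout metric between epochs
#'
#' For each trial, (mean during - mean before) / mean before of the chosen
#' metric, as used to quantify the effect of optogenetic manipulation on
#' locomotion speed and propulsion efficiency. The output table is suitable
#' for a zero-median sign or signed-rank test.
#'
#' @param bouts_pre,bouts_during data.frames of bouts with the metric column
#'   and, optionally, a \code{trial} column; without one, all bouts form a
#'   single trial.
#' @param metric "V_a" or "efficiency".
#' @return data.frame(trial, pre_mean, during_mean, frac_change).
#' @export
epoch_fractional_change <- function(bouts_pre, bouts_during,
                                    metric = c("V_a", "efficiency")) {
  metric <- match.arg(metric)
  if (nrow(bouts_pre) == 0 || nrow(bouts_during) == 0)
    stop("both epochs must contain at least one bout")
  if (is.null(bouts_pre$trial)) bouts_pre$trial <- 1L
  if (is.null(bouts_during$trial)) bouts_during$trial <- 1L
  trials <- intersect(unique(bouts_pre$trial), unique(bouts_during$trial))
  if (length(trials) == 0) stop("no trial present in both epochs")
  out <- lapply(trials, function(tr) {
    pre <- mean(bouts_pre[[metric]][bouts_pre$trial == tr])
    dur <- mean(bouts_during[[metric]][bouts_during$trial == tr])
    if (!is.finite(pre) || pre == 0)
      stop(sprintf("zero pre-epoch mean for trial %s", tr))
    data.frame(trial = tr, pre_mean = pre, during_mean = dur,
               frac_change = (dur - pre) / pre)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
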