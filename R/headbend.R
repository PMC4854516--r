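# Head-bending measures: curvature-based amplitude (free locomotion) and the
# ellipse-orientation bending index (microfluidic recordings).

new_bending_trace <- function(values, frame_rate, normalized = FALSE) {
  structure(list(values = values, frame_rate = frame_rate,
                 normalized = normalized, ventral_positive = TRUE),
            class = "bending_trace")
}

#' @export
print.bending_trace <- function(x, ...) {
  cat(sprintf("bending trace: %d frames at %.3g Hz (%s), %d missing\n",
              length(x$values), x$frame_rate,
              if (x$normalized) "normalised index" else "head curvature",
              sum(!is.finite(x$values))))
  invisible(x)
}

#' Head-curvature time series from a kymograph
#'
#' The head region is the first 18 of 100 segments (the anterior 18\% of the
#' body from the nose tip); head curvature is their per-frame mean. Missing
#' frames propagate as missing.
#'
#' @param kymograph a \code{curvature_kymograph} with >= \code{n_head} columns.
#' @param n_head number of anterior segments in the head region.
#' @return a \code{bending_trace} of dimensionless head curvature.
#' @export
head_curvature <- function(kymograph, n_head = 18L) {
  if (ncol(kymograph) < n_head)
    stop(sprintf("kymograph has %d segments; need at least %d",
                 ncol(kymograph), n_head))
  v <- rowMeans(unclass(kymograph)[, seq_len(n_head), drop = FALSE])
  new_bending_trace(v, attr(kymograph, "frame_rate"))
}

#' Head bending amplitude
#'
#' The amplitude of head bending over a measurement lapse is the population
#' standard deviation of the head-curvature trace (reversal and turn frames
#' are excluded upstream). For a pure sinusoid of amplitude A this converges
#' to A/sqrt(2).
#'
#' @param trace a \code{bending_trace} (or numeric vector).
#' @param min_frames minimum number of finite frames required; the default
#'   corresponds to 30 s at 5 Hz.
#' @return scalar amplitude (dimensionless curvature).
#' @export
head_bending_amplitude <- function(trace, min_frames = 150L) {
  v <- if (inherits(trace, "bending_trace")) trace$values else as.numeric(trace)
  n_ok <- sum(is.finite(v))
  if (n_ok < min_frames)
    stop(sprintf("too few frames for amplitude: %d finite, need >= %d",
                 n_ok, min_frames))
  pop_sd(v)
}

# Orientation (radians, in (-pi/2, pi/2]) of the foreground of a binary mask,
# from second-order central moments of pixel coordinates.
mask_orientation <- function(mask, min_elongation = 1.05) {
  rc <- which(mask, arr.ind = TRUE)
  if (nrow(rc) < 3) return(NA_real_)
  xy <- cbind(rc[, 2], -rc[, 1])     # x right, y up
  cv <- stats::cov(xy)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] <= 0 || ev$values[1] / ev$values[2] < min_elongation)
    return(NA_real_)                 # near-circular: orientation undefined
  v <- ev$vectors[, 1]
  atan2(v[2], v[1]) %% pi            # line orientation, mod pi
}

#' Ellipse-orientation head-bending index
#'
#' For movies of a head ROI, fits the foreground to an ellipse via second
#' moments, measures its orientation per frame, subtracts the orientation of
#' the reference frame (minimum head bending), and normalises by the maximum
#' absolute deflection so the index lies in [-1, 1], ventral positive.
#'
#' @param masks list of binary matrices (head-ROI masks per frame).
#' @param reference_frame "auto" (frame whose orientation is closest to the
#'   median) or a frame index.
#' @param frame_rate Hz.
#' @param ventral_sign +1/-1 flag mapping positive deflection to ventral.
#' @return a normalised \code{bending_trace}; degenerate frames are missing.
#' @export
ellipse_bending_index <- function(masks, reference_frame = "auto",
                                  frame_rate = 5, ventral_sign = 1) {
  ori <- vapply(masks, mask_orientation, 1)
  # unwrap the mod-pi line orientation to a continuous angle
  ok <- which(is.finite(ori))
  if (length(ok) < 2) stop("too few frames with a defined orientation")
  u <- ori[ok]
  d <- diff(u)
  d <- d - pi * round(d / pi)
  u <- u[1] + c(0, cumsum(d))
  ori[ok] <- u
  if (identical(reference_frame, "auto")) {
    med <- stats::median(ori, na.rm = TRUE)
    ref <- which.min(abs(ori - med))
  } else ref <- as.integer(reference_frame)
  if (!is.finite(ori[ref])) stop("reference frame has undefined orientation")
  defl <- ori - ori[ref]
  mx <- max(abs(defl), na.rm = TRUE)
  if (mx < 1e-9) {
    warning("constant orientation: zero maximum deflection, returning zeros")
    idx <- ifelse(is.finite(defl), 0, NA_real_)
  } else idx <- ventral_sign * defl / mx
  new_bending_trace(idx, frame_rate, normalized = TRUE)
}
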