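# Fluorescence trace extraction and normalisation.

#' Construct a fluorescence trace
#'
#' Holds the background-subtracted ROI intensity time series and its
#' per-recording extrema, used by the min-max normalisation.
#'
#' @param raw numeric vector of background-subtracted intensities (a.u.).
#' @param frame_rate Hz.
#' @return an object of class \code{fluor_trace} with fields \code{raw},
#'   \code{F_min}, \code{F_max}, \code{normalized} (filled by
#'   \code{\link{normalize_trace}}) and \code{frame_rate}.
#' @export
fluorescence_trace <- function(raw, frame_rate = 5) {
  raw <- as.numeric(raw)
  structure(list(raw = raw, F_min = min(raw), F_max = max(raw),
                 normalized = NULL, frame_rate = frame_rate),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("fluorescence trace: %d frames at %.3g Hz, F in [%.4g, %.4g]%s\n",
              length(x$raw), x$frame_rate, x$F_min, x$F_max,
              if (is.null(x$normalized)) "" else ", normalised"))
  invisible(x)
}

#' Background-subtracted total ROI intensity of one frame
#'
#' Total fluorescence is the sum over the ROI of (pixel - background), the
#' background being the mean of a non-overlapping background region (or a
#' supplied scalar estimate).
#'
#' @param frame numeric matrix (grayscale image).
#' @param roi logical matrix the size of \code{frame}, or a 2-column matrix of
#'   (row, col) indices.
#' @param background same formats as \code{roi}, or a single numeric value.
#' @return scalar intensity (a.u.).
#' @export
roi_intensity <- function(frame, roi, background) {
  roi_idx <- region_indices(roi, frame, "roi")
  if (length(roi_idx) == 0) stop("empty roi")
  if (is.numeric(background) && length(background) == 1 &&
      !is.matrix(background)) {
    bg <- background
  } else {
    bg_idx <- region_indices(background, frame, "background")
    if (length(bg_idx) == 0) stop("empty background region")
    if (length(intersect(roi_idx, bg_idx)) > 0)
      stop("roi and background regions overlap")
    bg <- mean(frame[bg_idx])
  }
  sum(frame[roi_idx] - bg)
}

region_indices <- function(region, frame, what) {
  if (is.logical(region)) {
    if (!all(dim(region) == dim(frame)))
      stop(sprintf("%s mask dimensions do not match the frame", what))
    which(region)
  } else if (is.matrix(region) && ncol(region) == 2) {
    (region[, 2] - 1L) * nrow(frame) + region[, 1]
  } else stop(sprintf("%s must be a logical mask or (row, col) index matrix",
                      what))
}

#' Extract a fluorescence trace from an image stack
#'
#' Applies \code{\link{roi_intensity}} to each frame of a pre-aligned stack.
#'
#' @param stack list of numeric matrices.
#' @param roi,background as in \code{\link{roi_intensity}}.
#' @param frame_rate Hz.
#' @return a \code{fluor_trace}.
#' @export
extract_trace <- function(stack, roi, background, frame_rate = 5) {
  raw <- vapply(stack, roi_intensity, 1, roi = roi, background = background)
  fluorescence_trace(raw, frame_rate)
}

#' Min-max normalise a fluorescence trace
#'
#' Normalises each individual recording to a linear scale by
#' (F - F_min) / (F_max - F_min), so the minimum maps to 0 and the maximum
#' to 1. Invariant under positive affine rescaling of the raw trace.
#'
#' @param trace a \code{fluor_trace} (or numeric vector).
#' @return the trace with its \code{normalized} field filled.
#' @export
normalize_trace <- function(trace) {
  if (!inherits(trace, "fluor_trace")) trace <- fluorescence_trace(trace)
  if (length(trace$raw) < 2) stop("need at least 2 frames to normalise")
  if (trace$F_max <= trace$F_min)
    stop("normalization error: constant trace (F_max equals F_min)")
  trace$normalized <- (trace$raw - trace$F_min) / (trace$F_max - trace$F_min)
  trace
}

#' Ratiometric trace (GCaMP over reference fluorophore)
#'
#' Elementwise ratio of two co-recorded channels; divides out shared
#' motion/expression artifacts such as bleaching applied to both channels.
#'
#' @param gcamp,reference \code{fluor_trace} objects of equal length and
#'   frame rate; the reference must be strictly positive.
#' @return numeric vector of dimensionless ratios.
#' @export
ratio_trace <- function(gcamp, reference) {
  stopifnot(inherits(gcamp, "fluor_trace"), inherits(reference, "fluor_trace"))
  if (length(gcamp$raw) != length(reference$raw))
    stop("traces must have equal length")
  if (gcamp$frame_rate != reference$frame_rate)
    stop("traces must share a frame rate")
  if (any(reference$raw <= 0))
    stop("reference trace must be strictly positive")
  gcamp$raw / reference$raw
}
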