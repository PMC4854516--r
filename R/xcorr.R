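# Cross-correlation of behaviour and calcium traces, and the signed
# peak-correlation statistic taken in a window around a reference lag.

trace_values <- function(x) {
  if (inherits(x, "bending_trace")) return(x$values)
  if (inherits(x, "fluor_trace"))
    return(if (!is.null(x$normalized)) x$normalized else x$raw)
  as.numeric(x)
}

trace_rate <- function(x, default = NULL) {
  if (inherits(x, "bending_trace")) return(x$frame_rate)
  if (inherits(x, "fluor_trace")) return(x$frame_rate)
  default
}

#' Lagged Pearson cross-correlation of two traces
#'
#' Computes the Pearson correlation at every integer-frame lag up to
#' \code{max_lag} seconds (default 20 s, i.e. 100 frames at 5 Hz). Each
#' series is mean-centred and variance-normalised over the overlapping window
#' of each lag, so every coefficient is a bona fide correlation in [-1, 1];
#' missing frames are pairwise-deleted. A positive lag means the response
#' follows the input (the behaviour trace is the input).
#'
#' @param input the behavioural \code{bending_trace} (or numeric vector).
#' @param response the normalised \code{fluor_trace} (or numeric vector).
#' @param max_lag seconds.
#' @param frame_rate Hz; taken from the traces when they carry one.
#' @return a \code{correlogram}: data.frame(lag_s, coef) with attributes
#'   \code{frame_rate}, \code{input_label} and \code{T_p} (NA until set).
#' @export
cross_correlate <- function(input, response, max_lag = 20, frame_rate = NULL) {
  fr_in <- trace_rate(input); fr_out <- trace_rate(response)
  fr <- frame_rate %||% fr_in %||% fr_out
  if (is.null(fr)) stop("frame_rate is required for plain numeric traces")
  if (!is.null(fr_in) && !is.null(fr_out) && fr_in != fr_out)
    stop("input and response frame rates differ")
  x <- trace_values(input); y <- trace_values(response)
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  if (n / fr < 2 * max_lag)
    warning("overlapping duration shorter than twice the maximum lag")
  L <- round(max_lag * fr)
  lags <- (-L):L
  cc <- vapply(lags, function(l) {
    if (abs(l) >= n - 2) return(NA_real_)
    if (l >= 0) { xs <- x[seq_len(n - l)]; ys <- y[seq_len(n - l) + l] }
    else        { xs <- x[seq_len(n + l) - l]; ys <- y[seq_len(n + l)] }
    ok <- is.finite(xs) & is.finite(ys)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(xs[ok]) == 0 || stats::sd(ys[ok]) == 0) return(NA_real_)
    stats::cor(xs[ok], ys[ok])
  }, 1)
  if (all(!is.finite(cc)))
    stop("zero-variance overlap window: correlation undefined at every lag")
  structure(data.frame(lag_s = lags / fr, coef = cc),
            frame_rate = fr, input_label = "behaviour", T_p = NA_real_,
            class = c("correlogram", "data.frame"))
}

#' @export
print.correlogram <- function(x, ...) {
  i <- which.max(abs(x$coef))
  cat(sprintf("correlogram: lags %+.3g..%+.3g s at %.3g Hz; extreme %.3f at %+.3g s\n",
              min(x$lag_s), max(x$lag_s), attr(x, "frame_rate"),
              x$coef[i], x$lag_s[i]))
  invisible(x)
}

#' Reference peak lag of a control group
#'
#' Averages a collection of correlograms on a common lag grid and returns the
#' lag T_p of the maximum absolute mean coefficient, used as the reference
#' around which group peak correlations are read.
#'
#' @param correlograms list of \code{correlogram} objects (or a single one).
#' @return T_p in seconds.
#' @export
reference_peak <- function(correlograms) {
  if (inherits(correlograms, "correlogram"))
    correlograms <- list(correlograms)
  if (length(correlograms) == 0) stop("empty correlogram collection")
  lag0 <- correlograms[[1]]$lag_s
  for (cg in correlograms)
    if (!isTRUE(all.equal(cg$lag_s, lag0)))
      stop("correlograms are not on a common lag grid")
  mu <- rowMeans(vapply(correlograms, function(cg) cg$coef,
                        numeric(length(lag0))), na.rm = TRUE)
  amax <- max(abs(mu), na.rm = TRUE)
  cand <- which(is.finite(mu) & abs(mu) >= amax - 1e-12)
  # periodic or symmetric correlograms tie at several lags: prefer the lag
  # closest to zero, and the non-negative one on an exact mirror tie
  cand <- cand[order(abs(lag0[cand]), lag0[cand] < 0)]
  lag0[cand[1]]
}

#' Signed peak correlation in a window around T_p
#'
#' Within the closed window [T_p - window/2, T_p + window/2] (1 s, i.e. 5
#' lags at 5 Hz, by default), returns the coefficient of maximum absolute
#' value with its sign preserved, plus its lag. Ties break toward the lag
#' nearest T_p.
#'
#' @param correlogram a \code{correlogram}.
#' @param T_p reference lag in seconds.
#' @param window window width in seconds.
#' @return list(value, lag).
#' @export
peak_correlation <- function(correlogram, T_p, window = 1) {
  lag <- correlogram$lag_s
  tol <- 1e-9
  if (T_p - window / 2 < min(lag) - tol || T_p + window / 2 > max(lag) + tol)
    stop("window extends beyond the correlogram's lag range")
  inw <- which(lag >= T_p - window / 2 - tol & lag <= T_p + window / 2 + tol)
  co <- correlogram$coef[inw]
  if (all(!is.finite(co))) stop("all coefficients missing within the window")
  amax <- max(abs(co), na.rm = TRUE)
  cand <- inw[which(is.finite(co) & abs(co) >= amax - tol)]
  best <- cand[which.min(abs(lag[cand] - T_p))]
  list(value = correlogram$coef[best], lag = lag[best])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
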