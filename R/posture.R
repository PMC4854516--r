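# Posture extraction: binary mask -> boundary -> head/tail endpoints ->
# centerline -> signed curvature kymograph.

#' Binarise a grayscale frame to a single-worm mask
#'
#' Thresholds the image (Otsu or fixed), keeps the largest connected
#' foreground component and fills its holes.
#'
#' @param image numeric matrix (rows x cols); any intensity range.
#' @param method "otsu" or "fixed".
#' @param threshold required for \code{method = "fixed"}, on the scale of
#'   \code{image}.
#' @param mm_per_px pixel size carried into the frame.
#' @param timestamp acquisition time in seconds.
#' @return a \code{worm_frame}.
#' @export
binarize_frame <- function(image, method = c("otsu", "fixed"),
                           threshold = NULL, mm_per_px = 0.01, timestamp = 0) {
  method <- match.arg(method)
  if (length(image) == 0) stop("empty image")
  rng <- range(image, finite = TRUE)
  if (method == "otsu") {
    if (rng[2] <= rng[1]) stop("segmentation error: image has no contrast")
    scaled <- (image - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(t(scaled)))
    mask <- scaled > thr
  } else {
    if (is.null(threshold)) stop_config("threshold", "is required for method 'fixed'")
    mask <- image > threshold
  }
  if (!any(mask)) stop("segmentation error: empty foreground")
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  tab <- tabulate(as.integer(lab))
  keep <- which.max(tab)
  comp <- EBImage::fillHull(lab == keep)
  mask <- t(comp@.Data > 0)
  new_worm_frame(mask, timestamp = timestamp, mm_per_px = mm_per_px)
}

# Ordered boundary of the mask, arclength-resampled and lightly smoothed.
# Returns CCW-oriented mm coordinates plus the smoothed signed curvature.
worm_boundary <- function(frame, smooth_frac = 0.02, n_out = NULL) {
  mask <- frame$mask
  oc <- EBImage::ocontour(EBImage::Image(t(mask)))
  oc <- oc[[which.max(vapply(oc, nrow, 1L))]]
  nr <- nrow(mask)
  xy <- cbind((oc[, 1] + 0.5) * frame$mm_per_px,
              (nr - oc[, 2] - 0.5) * frame$mm_per_px)
  # ensure counter-clockwise so convex boundary curvature is positive
  a <- sum(xy[, 1] * c(xy[-1, 2], xy[1, 2]) - c(xy[-1, 1], xy[1, 1]) * xy[, 2])
  if (a < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  # resample closed polygon to uniform arclength
  seg <- sqrt(rowSums((rbind(xy[-1, ], xy[1, ]) - xy)^2))
  per <- sum(seg)
  m <- if (is.null(n_out)) max(200L, nrow(xy)) else n_out
  cum <- c(0, cumsum(seg))
  tgt <- seq(0, per, length.out = m + 1)[-(m + 1)]
  xs <- stats::approx(cum, c(xy[, 1], xy[1, 1]), xout = tgt)$y
  ys <- stats::approx(cum, c(xy[, 2], xy[1, 2]), xout = tgt)$y
  raw <- cbind(x = xs, y = ys)
  # circular moving-average smoothing, window ~ smooth_frac of perimeter
  w <- max(3L, round(smooth_frac * m))
  if (w %% 2 == 0) w <- w + 1L
  ker <- rep(1 / w, w)
  csm <- function(v) {
    ext <- c(v[(m - (w %/% 2) + 1):m], v, v[1:(w %/% 2)])
    stats::filter(ext, ker, sides = 2)[(w %/% 2 + 1):(w %/% 2 + m)]
  }
  xs <- csm(xs); ys <- csm(ys)
  h <- per / m
  idx <- seq_len(m)
  ip <- c(idx[-1], 1L); im <- c(m, idx[-m])
  dx <- (xs[ip] - xs[im]) / (2 * h); dy <- (ys[ip] - ys[im]) / (2 * h)
  ddx <- (xs[ip] - 2 * xs + xs[im]) / h^2
  ddy <- (ys[ip] - 2 * ys + ys[im]) / h^2
  kap <- (dx * ddy - dy * ddx) / pmax((dx^2 + dy^2)^1.5, 1e-12)
  list(points = cbind(x = xs, y = ys), points_raw = raw, curvature = kap,
       perimeter = per, spacing = h)
}

#' Locate worm endpoints as convex boundary-curvature extrema
#'
#' The head and tail are the two boundary positions of maximum convex
#' curvature, required to be separated by at least a quarter of the perimeter
#' (which rejects the outer apex of a deep body bend).
#'
#' @param frame a \code{worm_frame}.
#' @param smooth_frac boundary smoothing window as a fraction of perimeter.
#' @param peak_factor a convex peak must exceed this multiple of the curvature
#'   of a circle with the same perimeter.
#' @return 2 x 2 matrix of endpoint (x, y) mm coordinates, with the boundary
#'   attached as attribute \code{boundary} and indices as \code{index}.
#' @export
find_endpoints <- function(frame, smooth_frac = 0.02, peak_factor = 2.5) {
  # a near-circular blob has no head or tail: gate on the isoperimetric
  # ratio before looking for curvature extrema
  bd <- worm_boundary(frame, smooth_frac)
  area <- sum(frame$mask) * frame$mm_per_px^2
  if (bd$perimeter^2 / (4 * pi * area) < 1.5)
    stop("endpoint-detection error: near-circular blob, no convex endpoints")
  kap <- bd$curvature
  m <- length(kap)
  thr <- peak_factor * 2 * pi / bd$perimeter
  ip <- c(2:m, 1L); im <- c(m, 1:(m - 1))
  is_peak <- kap > thr & kap >= kap[ip] & kap >= kap[im]
  peaks <- which(is_peak)
  if (length(peaks) < 2)
    stop("endpoint-detection error: fewer than two convex curvature peaks")
  # first endpoint: global convex-curvature maximum; second: the strongest
  # peak at least a quarter perimeter away (rejects stair-step noise and the
  # outer apex of a body bend, which sit close to a tip or are much flatter)
  p1 <- peaks[which.max(kap[peaks])]
  sep <- pmin(abs(peaks - p1), m - abs(peaks - p1))
  cand <- peaks[sep >= 0.25 * m]
  if (length(cand) == 0)
    stop("endpoint-detection error: candidate endpoints are not well separated")
  p2 <- cand[which.max(kap[cand])]
  # rounded caps smear the curvature peak along the cap: snap each endpoint
  # to the geometric apex of its tip, at sub-pixel resolution
  r1 <- refine_tip(bd, p1, px = frame$mm_per_px)
  r2 <- refine_tip(bd, p2, px = frame$mm_per_px)
  ep <- rbind(r1$pos, r2$pos)
  structure(ep, index = c(r1$index, r2$index), boundary = bd)
}

# Locate the geometric apex of a tip near boundary index p: the midpoint of
# the chord joining the ends of a +-frac perimeter neighbourhood lies inside
# the body just behind the tip, so the boundary point farthest from it is
# the apex. Rounded caps hold several near-farthest points; their centroid
# gives the apex at sub-pixel resolution.
refine_tip <- function(bd, p, frac = 0.1, iterations = 2L, px = 0.005) {
  m <- nrow(bd$points_raw)
  k <- max(3L, round(frac * m))
  for (it in seq_len(iterations)) {
    idx <- ((p - k - 1):(p + k - 1)) %% m + 1L
    pts <- bd$points_raw[idx, , drop = FALSE]
    ctr <- (pts[1, ] + pts[nrow(pts), ]) / 2
    d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    p <- idx[which.max(d)]
  }
  near <- d >= max(d) - 0.35 * px
  list(index = p, pos = colMeans(pts[near, , drop = FALSE]))
}

#' Extract an arclength-resampled centerline between two endpoints
#'
#' Splits the ordered boundary at the endpoints into two flanks and builds
#' the midline in stages: nearest-point correspondences between the flanks,
#' normal-intersection relaxation passes that recentre each point between
#' the two boundary crossings of its normal, trimming of the degenerate tip
#' neighbourhoods, cubic smoothing-spline fitting of the tangent angle
#' (with local-quadratic padding so the spline's natural boundary
#' conditions do not flatten the tip curvature), and constant-curvature
#' bridges that continue the interior bend out to the detected tip apexes.
#' The result is resampled to \code{n_segments + 1} equally spaced points
#' from head to tail.
#'
#' @param frame a \code{worm_frame}.
#' @param head,tail endpoint (x, y) positions in mm (from
#'   \code{\link{find_endpoints}}, in either order).
#' @param n_segments number of body segments (points = n_segments + 1).
#' @param smooth_df equivalent degrees of freedom of the tangent-angle
#'   smoothing spline; NULL disables smoothing.
#' @param endpoints optional result of \code{\link{find_endpoints}} to reuse.
#' @return a \code{centerline}.
#' @export
extract_centerline <- function(frame, head, tail, n_segments = 100L,
                               smooth_df = 16, endpoints = NULL) {
  if (is.null(endpoints)) endpoints <- find_endpoints(frame)
  bd <- attr(endpoints, "boundary")
  idx <- attr(endpoints, "index")
  pts <- bd$points
  m <- nrow(pts)
  # match supplied head/tail to detected endpoints
  d_head <- colSums((t(unclass(endpoints)[, 1:2, drop = FALSE]) - head)^2)
  w_head <- which.min(d_head)
  i_head <- idx[w_head]
  i_tail <- idx[-w_head][1]
  hd_apex <- unclass(endpoints)[w_head, 1:2]
  tl_apex <- unclass(endpoints)[-w_head, 1:2, drop = FALSE][1, ]
  if (i_head == i_tail) stop("centerline error: endpoints coincide")
  fwd <- if (i_head < i_tail) i_head:i_tail else c(i_head:m, 1:i_tail)
  bwd <- if (i_head < i_tail) c(i_head:1, m:i_tail) else i_head:i_tail
  A <- resample_polyline(pts[fwd, , drop = FALSE], 301L)
  B <- resample_polyline(pts[bwd, , drop = FALSE], 601L)
  # midline = midpoints of nearest-point correspondences A -> B
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  j <- max.col(-d2, ties.method = "first")
  mid <- (A + B[j, , drop = FALSE]) / 2
  mid <- mid[!duplicated(round(mid / (frame$mm_per_px / 4))), , drop = FALSE]
  mid <- resample_polyline(mid, 401L)
  # relax the midline: recentre each point at the midpoint of the two
  # boundary intersections of its normal (removes the bias of the
  # nearest-point correspondences where the body bends or tapers)
  for (pass in 1:3) mid <- recentre_midline(mid, pts)
  # the midline is unreliable where the body tapers into the tips (the
  # normals stop crossing both flanks and the cross-body correspondences
  # cluster): trim it, smooth the rest with a short moving average, and
  # drop the edge points whose windows were padded -- residual jitter
  # there can reverse a chord and corrupt the tangent angle
  trim <- 5L
  mid <- mid[(trim + 1):(401L - trim), , drop = FALSE]
  mid <- smooth_polyline(mid, 7L)
  mid <- mid[6:(nrow(mid) - 5L), , drop = FALSE]
  seg <- diff(mid)
  ds <- sqrt(rowSums(seg^2))
  total <- sum(ds)
  if (total <= 0) stop("centerline error: degenerate midline")
  # smooth the tangent angle with a cubic smoothing spline; the angle is
  # sampled on two-point-span chords (a single jittered point cannot
  # reverse them, which would slip the unwrapping by a full turn), and
  # local-quadratic padding beyond both ends keeps the spline's natural
  # boundary conditions from flattening d(psi)/ds (the curvature) there
  M <- nrow(mid)
  cum <- c(0, cumsum(ds))
  seg2 <- mid[3:M, , drop = FALSE] - mid[1:(M - 2), , drop = FALSE]
  psi <- unwrap(atan2(seg2[, 2], seg2[, 1]))
  smid <- (cum[3:M] + cum[1:(M - 2)]) / 2
  np <- length(psi)
  if (!is.null(smooth_df) && smooth_df > 0) {
    kfit <- min(np, round(0.15 * np))
    qcoef <- function(ii) stats::lm.fit(cbind(1, smid[ii], smid[ii]^2),
                                        psi[ii])$coefficients
    co_head <- qcoef(1:kfit)
    co_tail <- qcoef((np - kfit + 1):np)
    k <- min(np - 1L, round(0.06 * np))
    s_head <- smid[1] - rev(seq_len(k)) * (smid[2] - smid[1])
    s_tail <- smid[np] + seq_len(k) * (smid[np] - smid[np - 1])
    s_ext <- c(s_head, smid, s_tail)
    p_ext <- c(co_head[1] + co_head[2] * s_head + co_head[3] * s_head^2,
               psi,
               co_tail[1] + co_tail[2] * s_tail + co_tail[3] * s_tail^2)
    df_ext <- min(smooth_df * (np + 2 * k) / np, length(p_ext) - 1)
    fit <- stats::smooth.spline(s_ext, p_ext, df = df_ext)
    psi <- stats::predict(fit, smid)$y
  }
  # rebuild positions from the head anchor with uniform steps; the smoothed
  # tangent angle integrates with a small drift, so redistribute the
  # closure mismatch linearly to re-anchor the tail end
  step <- total / np
  path <- cbind(mid[1, 1] + c(0, cumsum(step * cos(psi))),
                mid[1, 2] + c(0, cumsum(step * sin(psi))))
  npth <- nrow(path)
  gap <- mid[nrow(mid), ] - path[npth, ]
  path <- path + outer((seq_len(npth) - 1) / (npth - 1), gap)
  # bridge from the trimmed midline ends toward the tip apexes with the
  # constant-curvature continuation of the interior bend; the bridge length
  # comes from the apex but its shape does not, so apex pixel noise cannot
  # inject curvature into the tip segments
  kfit <- min(np, round(0.15 * np))
  # turning rate for the bridge: a local quadratic fit of the tangent angle
  # supplies the curvature and its gradient at the junction, each shrunk by
  # its standard error so noise on a straight body does not bend the bridge
  qfit_at <- function(ii, s0) {
    X <- cbind(1, smid[ii], smid[ii]^2)
    fit <- stats::lm.fit(X, psi[ii])
    co <- fit$coefficients
    sig2 <- sum(fit$residuals^2) / max(1, length(ii) - 3)
    XtXi <- chol2inv(chol(crossprod(X)))
    shrink <- function(cc) {
      est <- drop(cc %*% co)
      se2 <- sig2 * drop(cc %*% XtXi %*% cc)
      est * est^2 / (est^2 + 9 * se2)
    }
    list(value = drop(c(1, s0, s0^2) %*% co),
         deriv = shrink(c(0, 1, 2 * s0)), curv = shrink(c(0, 0, 2)))
  }
  qh <- qfit_at(1:kfit, smid[1])
  qt <- qfit_at((np - kfit + 1):np, smid[np])
  head_br <- tip_bridge(path[1, ], qh$value + pi, -qh$deriv, 0, hd_apex)
  tail_br <- tip_bridge(path[npth, ], qt$value, qt$deriv, 0, tl_apex)
  path <- rbind(head_br[rev(seq_len(nrow(head_br))), , drop = FALSE],
                path, tail_br)
  out <- resample_polyline(path, n_segments + 1L)
  seg_len <- sum(sqrt(rowSums(diff(path)^2)))
  new_centerline(cbind(x = out[, 1], y = out[, 2]),
                 arclength = seg_len, frame_index = frame$timestamp)
}

# Constant-curvature continuation from point p0 with heading h0 and turning
# rate kap, walked for the length of the apex's projection on the heading.
tip_bridge <- function(p0, h0, kap, dkap, apex, n_pts = 8L) {
  len <- sum((apex - p0) * c(cos(h0), sin(h0)))
  if (!is.finite(len) || len <= 1e-9) return(matrix(numeric(0), 0, 2))
  sm <- (seq_len(n_pts) - 0.5) / n_pts * len
  ang <- h0 + kap * sm + dkap * sm^2 / 2
  cbind(p0[1] + cumsum(len / n_pts * cos(ang)),
        p0[2] + cumsum(len / n_pts * sin(ang)))
}

# One midline relaxation pass: move each midline point to the midpoint of
# the nearest boundary intersections of its local normal. Points whose
# normal does not cross the boundary on both sides are left unchanged.
recentre_midline <- function(mid, boundary) {
  n <- nrow(mid)
  seg <- diff(mid)
  tang <- rbind(seg[1, , drop = FALSE],
                (seg[-1, , drop = FALSE] + seg[-(n - 1), , drop = FALSE]) / 2,
                seg[n - 1, , drop = FALSE])
  tang <- tang / sqrt(rowSums(tang^2))
  q1x <- boundary[, 1]; q1y <- boundary[, 2]
  q2x <- c(q1x[-1], q1x[1]); q2y <- c(q1y[-1], q1y[1])
  dx <- q2x - q1x; dy <- q2y - q1y
  tpos <- rep(NA_real_, n); tneg <- rep(NA_real_, n)
  nrm <- cbind(-tang[, 2], tang[, 1])
  for (i in seq_len(n)) {
    nx <- nrm[i, 1]; ny <- nrm[i, 2]
    den <- nx * dy - ny * dx
    wx <- q1x - mid[i, 1]; wy <- q1y - mid[i, 2]
    tt <- (wx * dy - wy * dx) / den
    uu <- (wx * ny - wy * nx) / den
    hit <- is.finite(tt) & uu >= 0 & uu < 1 & abs(den) > 1e-12
    tp <- suppressWarnings(min(tt[hit & tt > 0]))
    tn <- suppressWarnings(max(tt[hit & tt < 0]))
    if (is.finite(tp) && is.finite(tn)) { tpos[i] <- tp; tneg[i] <- tn }
  }
  # accept only plausible recentring moves: near the tips the normals graze
  # the cap and the intersection midpoint can jump far off the body
  halfw <- (tpos - tneg) / 2
  move <- (tpos + tneg) / 2
  w_med <- stats::median(halfw, na.rm = TRUE)
  ok <- is.finite(move) & halfw <= 2 * w_med & abs(move) <= 0.75 * w_med
  out <- mid
  out[ok, ] <- mid[ok, ] + move[ok] * nrm[ok, , drop = FALSE]
  out
}

# Moving-average an open polyline with an odd window, replicating the end
# points so the curve keeps its anchors.
smooth_polyline <- function(pts, w) {
  if (w < 3 || nrow(pts) <= w) return(pts)
  half <- w %/% 2
  pad <- rbind(pts[rep(1, half), , drop = FALSE], pts,
               pts[rep(nrow(pts), half), , drop = FALSE])
  ker <- rep(1 / w, w)
  out <- cbind(stats::filter(pad[, 1], ker, sides = 2),
               stats::filter(pad[, 2], ker, sides = 2))
  out[(half + 1):(half + nrow(pts)), , drop = FALSE]
}

# Resample an open polyline to n points uniformly spaced in arclength.
resample_polyline <- function(pts, n) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  tgt <- seq(0, cum[length(cum)], length.out = n)
  cbind(stats::approx(cum, pts[, 1], xout = tgt, ties = "ordered")$y,
        stats::approx(cum, pts[, 2], xout = tgt, ties = "ordered")$y)
}

#' Signed dimensionless curvature along a centerline
#'
#' Computes kappa_i = d psi / d s at each of the n segments and multiplies by
#' the arclength L, giving body-length-normalised curvature kappa*L. With the
#' image y axis pointing upward, positive curvature is a left turn of the
#' head-to-tail tangent; set \code{ventral_sign = -1} when the ventral side
#' faces the other way so that ventral bending is positive.
#'
#' @param centerline a \code{centerline} of n+1 points.
#' @param ventral_sign +1 or -1 dorsoventral orientation flag.
#' @return numeric vector of n signed kappa*L values.
#' @export
compute_curvature <- function(centerline, ventral_sign = 1) {
  pts <- unclass(centerline)[, 1:2, drop = FALSE]
  seg <- diff(pts)
  ds <- sqrt(rowSums(seg^2))
  L <- sum(ds)
  if (L <= 0) stop("degenerate centerline with zero length")
  n <- nrow(seg)
  psi <- unwrap(atan2(seg[, 2], seg[, 1]))
  h <- L / n
  kap <- numeric(n)
  if (n >= 3) {
    kap[2:(n - 1)] <- (psi[3:n] - psi[1:(n - 2)]) / (2 * h)
    # second-order one-sided differences at the end segments
    kap[1] <- (-3 * psi[1] + 4 * psi[2] - psi[3]) / (2 * h)
    kap[n] <- (3 * psi[n] - 4 * psi[n - 1] + psi[n - 2]) / (2 * h)
  } else kap[] <- 0
  ventral_sign * kap * L
}

#' Decide which end of a tracked worm is the head
#'
#' The head is the end from which the curvature wave propagates during forward
#' locomotion: the phase of the bending wave leads at the head. Estimated from
#' the phase-lag slope of the kymograph across interior segments.
#'
#' @param kymograph a provisional \code{curvature_kymograph} (>= 5 frames).
#' @param override "auto", or "first"/"last" to force the head end manually.
#' @param min_r2 minimum R^2 of the linear phase-lag fit.
#' @return list(head_end = "first" or "last", slope, r2, frequency).
#' @export
assign_head_tail <- function(kymograph, override = c("auto", "first", "last"),
                             min_r2 = 0.8) {
  override <- match.arg(override)
  if (override != "auto")
    return(list(head_end = override, slope = NA_real_, r2 = NA_real_,
                frequency = NA_real_))
  if (nrow(kymograph) < 5)
    stop("orientation error: need at least 5 frames of context")
  ps <- tryCatch(phase_slope(kymograph), error = function(e)
    stop("orientation error: ", conditionMessage(e), call. = FALSE))
  if (ps$concentration < 0.2 || ps$r2 < min_r2 || !is.finite(ps$slope))
    stop("orientation error: no significant wave-propagation phase gradient; assign the head manually")
  list(head_end = if (ps$slope < 0) "first" else "last",
       slope = ps$slope, r2 = ps$r2, frequency = ps$frequency)
}

# Cross-spectral phase-lag slope of the kymograph's travelling wave.
# Returns slope (rad per segment; negative = wave travels head->tail),
# interpolated dominant frequency (Hz), fit R^2 and spectral concentration.
phase_slope <- function(kymograph, seg_range = NULL) {
  mat <- unclass(kymograph)
  fr <- attr(kymograph, "frame_rate")
  ok <- stats::complete.cases(mat)
  mat <- mat[ok, , drop = FALSE]
  n <- nrow(mat)
  if (n < 5) stop("wave-speed error: too few complete frames")
  ncol_all <- ncol(mat)
  if (is.null(seg_range)) {
    lo <- max(1L, round(0.2 * ncol_all)); hi <- min(ncol_all, round(0.8 * ncol_all))
    seg_range <- lo:hi
  }
  mat <- mat[, seg_range, drop = FALSE]
  if (max(apply(mat, 2, stats::sd)) < 1e-9)
    stop("wave-speed error: no bending signal (static worm)")
  mat <- sweep(mat, 2, colMeans(mat))
  Z <- stats::mvfft(mat)
  nb <- floor(n / 2)
  if (nb < 2) stop("wave-speed error: record too short")
  pw <- rowMeans(Matrix_mod2(Z))[2:(nb + 1)]   # bins 1..nb (exclude DC)
  b <- which.max(pw)
  concentration <- pw[b] / sum(pw)
  # parabolic interpolation of the spectral peak
  delta <- 0
  if (b > 1 && b < nb) {
    al <- pw[b - 1]; be <- pw[b]; ga <- pw[b + 1]
    den <- al - 2 * be + ga
    if (den < 0) delta <- 0.5 * (al - ga) / den
  }
  frequency <- (b + delta) * fr / n
  phases <- unwrap(Arg(Z[b + 1L, ]))
  fit <- stats::lm.fit(cbind(1, seq_along(phases)), phases)
  slope <- fit$coefficients[2]
  ssr <- sum(fit$residuals^2)
  sst <- sum((phases - mean(phases))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  list(slope = unname(slope), frequency = frequency, r2 = r2,
       concentration = concentration, n_segments_total = ncol_all,
       seg_range = seg_range)
}

Matrix_mod2 <- function(Z) Re(Z)^2 + Im(Z)^2

#' Build a curvature kymograph from a single-worm movie
#'
#' Runs endpoint detection, centerline extraction and curvature computation on
#' every frame, tracks endpoint identity across frames by proximity, then
#' orients the whole movie head-first using the wave-propagation direction
#' (or a manual override). Failed frames are recorded as missing rows.
#'
#' @param frames list of \code{worm_frame} objects (or the \code{$frames}
#'   element of \code{\link{make_synthetic_movie}} output).
#' @param n_segments body segments per frame.
#' @param head_end "auto", "first" or "last".
#' @param smooth_df tangent-angle smoothing spline df.
#' @param ventral_sign dorsoventral orientation flag (+1/-1).
#' @param max_fail_frac maximum tolerated fraction of failed frames.
#' @return a \code{curvature_kymograph} with attributes \code{frame_lengths},
#'   \code{failed_frames} and \code{track} (centroid positions in mm).
#' @export
build_kymograph <- function(frames, n_segments = 100L,
                            head_end = c("auto", "first", "last"),
                            smooth_df = 16, ventral_sign = 1,
                            max_fail_frac = 0.2) {
  head_end <- match.arg(head_end)
  if (is.list(frames) && !is.null(frames$frames)) frames <- frames$frames
  nf <- length(frames)
  if (nf < 2) stop("need at least 2 frames")
  ts <- vapply(frames, function(f) f$timestamp, 1)
  if (any(diff(ts) < 0)) stop("timestamps must be non-decreasing")
  fr <- 1 / stats::median(diff(ts))
  K <- matrix(NA_real_, nf, n_segments)
  lens <- rep(NA_real_, nf)
  track <- matrix(NA_real_, nf, 2)
  prev_head <- NULL
  failed <- integer(0)
  for (i in seq_len(nf)) {
    res <- tryCatch({
      f <- frames[[i]]
      ep <- find_endpoints(f)
      if (is.null(prev_head)) {
        hd <- ep[1, ]; tl <- ep[2, ]
      } else {
        d <- sqrt(rowSums(sweep(ep, 2, prev_head)^2))
        hd <- ep[which.min(d), ]; tl <- ep[which.max(d), ]
      }
      cl <- extract_centerline(f, hd, tl, n_segments = n_segments,
                               smooth_df = smooth_df, endpoints = ep)
      rc <- which(f$mask, arr.ind = TRUE)
      ctr <- colMeans(px_to_mm(rc, nrow(f$mask), f$mm_per_px))
      list(k = compute_curvature(cl, ventral_sign), head = hd,
           len = attr(cl, "arclength"), ctr = ctr)
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- c(failed, i); next }
    K[i, ] <- res$k
    lens[i] <- res$len
    track[i, ] <- res$ctr
    prev_head <- res$head
  }
  if (length(failed) > nf * max_fail_frac)
    stop(sprintf("quality error: %d of %d frames failed posture extraction",
                 length(failed), nf))
  kym <- new_kymograph(K, fr, stats::median(lens, na.rm = TRUE),
                       frame_lengths = lens)
  ht <- assign_head_tail(kym, override = head_end)
  if (ht$head_end == "last") {
    K <- -K[, rev(seq_len(ncol(K))), drop = FALSE]
    kym <- new_kymograph(K, fr, attr(kym, "body_length"),
                         frame_lengths = lens)
  }
  attr(kym, "failed_frames") <- failed
  attr(kym, "track") <- data.frame(time_s = ts, x = track[, 1], y = track[, 2])
  attr(kym, "orientation") <- ht
  kym
}
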