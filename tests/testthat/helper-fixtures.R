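# Shared fixture builders. Everything is generated in code at test time.

# Centerlines with a directly prescribed sinusoidal tangent angle
# psi(s, t) = theta0 * sin(2 pi (s / lam - f t)), body length 1 mm.
prescribed_psi_centerlines <- function(theta0, lam, times, n = 200) {
  lapply(times, function(ft) {
    s <- (seq_len(n) - 0.5) / n
    psi <- theta0 * sin(2 * pi * (s / lam - ft))
    x <- c(0, cumsum(cos(psi) / n))
    y <- c(0, cumsum(sin(psi) / n))
    wormbend:::new_centerline(cbind(x = x, y = y), 1)
  })
}

# Elliptical ROI mask rotated by `ang` radians (for the bending index).
ellipse_mask <- function(ang, half = 60L, a = 48, b = 16) {
  n <- 2L * half + 1L
  xg <- matrix(rep(seq_len(n) - half - 1L, each = n), n, n)
  yg <- matrix(rep(half + 1L - seq_len(n), times = n), n, n)
  u <- xg * cos(ang) + yg * sin(ang)
  v <- -xg * sin(ang) + yg * cos(ang)
  (u / a)^2 + (v / b)^2 <= 1
}

# Hand-built correlogram on a 5 Hz lag grid.
toy_correlogram <- function(coefs, frame_rate = 5) {
  L <- (length(coefs) - 1) / 2
  structure(data.frame(lag_s = (-L:L) / frame_rate, coef = coefs),
            frame_rate = frame_rate, input_label = "behaviour",
            T_p = NA_real_, class = c("correlogram", "data.frame"))
}

# Short rendered movie used by several posture tests.
small_movie <- function(duration = 4, seed = 6, ...) {
  make_synthetic_movie(wave_params(duration = duration, seed = seed), ...)
}
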