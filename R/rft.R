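# Resistive force theory of undulatory locomotion: the small-angle
# efficiency curve, a numerical force-balance oracle, and the least-squares
# drag-ratio fit (the package's central estimator).

#' Small-angle RFT propulsion efficiency
#'
#' Propulsion efficiency of a slender undulator in a viscous fluid as a
#' function of the angle of attack, in the small-angle limit of resistive
#' force theory:
#'
#'   eta(theta_a; K) = (K - 1) q / (1 + K q),   q = (pi^2 / 8) theta_a^2
#'
#' with theta_a in radians and K = C_perp/C_par the drag-coefficient ratio.
#' q is the mean squared tangent angle of a sinusoidal wave whose mean
#' absolute tangent angle (the angle of attack) is theta_a. The curve
#' vanishes at theta_a = 0 and at K = 1 (isotropic drag gives no thrust) and
#' increases with theta_a over the small-angle range.
#'
#' @param theta_a angle of attack in degrees, in [0, 90).
#' @param K drag ratio C_perp/C_par (> 0).
#' @return efficiency V_a/V_w (dimensionless), vectorised over
#'   \code{theta_a}.
#' @export
rft_efficiency <- function(theta_a, K) {
  if (any(!is.finite(theta_a)) || any(theta_a < 0) || any(theta_a >= 90))
    stop("theta_a must lie in [0, 90) degrees")
  if (!is.numeric(K) || length(K) != 1 || !is.finite(K) || K <= 0)
    stop("K must be a single positive number")
  q <- (pi^2 / 8) * (theta_a * pi / 180)^2
  (K - 1) * q / (1 + K * q)
}

#' Numerical RFT force-balance simulation
#'
#' Independent oracle for the small-angle curve: prescribes periodic
#' centerline kinematics (by default a sinusoidal tangent-angle wave
#' travelling head to tail), applies local anisotropic drag per unit length
#' f = -C_par (u.t) t - C_perp (u.n) n, solves the zero-net-force and
#' zero-net-torque conditions for the instantaneous rigid translation and
#' rotation, and integrates the resulting rigid motion with RK4 over several
#' periods (discarding a transient).
#'
#' The closed-form small-angle curve assumes an infinite wave; prescribing
#' several wavelengths on the body (small \code{wavelength}) suppresses the
#' finite-body yaw and recoil that otherwise reduce the net speed.
#'
#' @param K drag ratio C_perp/C_par.
#' @param theta0_deg peak tangent angle of the wave in degrees (the angle of
#'   attack is (2/pi) theta0 for a sinusoid).
#' @param wavelength body lengths per spatial period.
#' @param frequency Hz.
#' @param body_length mm.
#' @param n_points discretisation of the body.
#' @param steps_per_period time steps per undulation period.
#' @param n_periods periods integrated.
#' @param discard_periods transient periods discarded before averaging.
#' @param wave_direction +1 for head-to-tail, -1 reversed.
#' @param psi_fun optional tangent-angle function psi(s, t) (s in [0, 1],
#'   t in seconds) overriding the sinusoid.
#' @return list(V_a, V_w, efficiency, theta_a, yaw_amplitude).
#' @export
rft_force_balance <- function(K, theta0_deg = 12, wavelength = 0.2,
                              frequency = 1, body_length = 1,
                              n_points = 151, steps_per_period = 200,
                              n_periods = 3, discard_periods = 1,
                              wave_direction = 1, psi_fun = NULL) {
  if (K <= 0) stop("K must be positive")
  th0 <- theta0_deg * pi / 180
  L <- body_length
  n <- n_points
  sg <- seq(0, 1, length.out = n)
  ds <- L / (n - 1)
  if (is.null(psi_fun))
    psi_fun <- function(s, t)
      th0 * sin(2 * pi * (s / wavelength - wave_direction * frequency * t))
  shape <- function(t) {
    psi <- psi_fun(sg, t)
    x <- c(0, cumsum(0.5 * (cos(psi[-n]) + cos(psi[-1])) * ds))
    y <- c(0, cumsum(0.5 * (sin(psi[-n]) + sin(psi[-1])) * ds))
    cbind(x, y)
  }
  Cpar <- 1; Cperp <- K
  deriv <- function(t, phi) {
    P0 <- shape(t)
    eps <- 1e-6 / frequency
    W <- (shape(t + eps) - shape(t - eps)) / (2 * eps)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    Pc <- sweep(P0, 2, colMeans(P0))
    r <- Pc %*% t(R)
    w <- sweep(W, 2, colMeans(W)) %*% t(R)  # centroid-removed deformation vel.
    Tb <- diff(P0)
    Tb <- rbind(Tb, Tb[n - 1, , drop = FALSE])
    Tb <- Tb / sqrt(rowSums(Tb^2))
    Tl <- Tb %*% t(R)
    Nl <- cbind(-Tl[, 2], Tl[, 1])
    D11 <- Cpar * Tl[, 1]^2 + Cperp * Nl[, 1]^2
    D12 <- Cpar * Tl[, 1] * Tl[, 2] + Cperp * Nl[, 1] * Nl[, 2]
    D22 <- Cpar * Tl[, 2]^2 + Cperp * Nl[, 2]^2
    rx <- r[, 1]; ry <- r[, 2]; vx <- w[, 1]; vy <- w[, 2]
    A <- rbind(
      c(sum(D11), sum(D12), sum(-D11 * ry + D12 * rx)),
      c(sum(D12), sum(D22), sum(-D12 * ry + D22 * rx)),
      c(sum(rx * D12 - ry * D11), sum(rx * D22 - ry * D12),
        sum(rx * (-D12 * ry + D22 * rx) - ry * (-D11 * ry + D12 * rx))))
    b <- -c(sum(D11 * vx + D12 * vy), sum(D12 * vx + D22 * vy),
            sum(rx * (D12 * vx + D22 * vy) - ry * (D11 * vx + D12 * vy)))
    sol <- tryCatch(solve(A, b), error = function(e)
      stop("numerical error: singular force-balance system"))
    list(U = sol[1:2], Om = sol[3])
  }
  dt <- 1 / (frequency * steps_per_period)
  nsteps <- round(n_periods * steps_per_period)
  pos <- c(0, 0); phi <- 0
  traj <- matrix(NA_real_, nsteps + 1, 2); traj[1, ] <- pos
  phis <- numeric(nsteps + 1)
  for (i in seq_len(nsteps)) {
    t <- (i - 1) * dt
    k1 <- deriv(t, phi)
    k2 <- deriv(t + dt / 2, phi + dt / 2 * k1$Om)
    k3 <- deriv(t + dt / 2, phi + dt / 2 * k2$Om)
    k4 <- deriv(t + dt, phi + dt * k3$Om)
    pos <- pos + dt / 6 * (k1$U + 2 * k2$U + 2 * k3$U + k4$U)
    phi <- phi + dt / 6 * (k1$Om + 2 * k2$Om + 2 * k3$Om + k4$Om)
    traj[i + 1, ] <- pos; phis[i + 1] <- phi
  }
  i0 <- round(discard_periods * steps_per_period) + 1L
  disp <- traj[nsteps + 1, ] - traj[i0, ]
  dur <- (nsteps + 1 - i0) * dt
  Va <- sqrt(sum(disp^2)) / dur
  Vw <- wavelength * L * frequency
  # angle of attack relative to the direction of motion, sampled over a period
  dirv <- if (Va > 1e-12) disp / sqrt(sum(disp^2)) else c(-1, 0)
  thsamp <- vapply(seq(0, 1 / frequency, length.out = 21)[-21], function(t) {
    P <- shape(t)
    seg <- diff(P); len <- sqrt(rowSums(seg^2))
    mean(acos(pmin(abs((seg[, 1] * dirv[1] + seg[, 2] * dirv[2]) / len), 1)))
  }, 1)
  list(V_a = Va, V_w = Vw, efficiency = Va / Vw,
       theta_a = mean(thsamp) * 180 / pi,
       yaw_amplitude = diff(range(phis[i0:(nsteps + 1)])) * 180 / pi,
       displacement = disp)
}

#' Fit the drag-coefficient ratio to bout data
#'
#' Least-squares fit of the single identifiable mechanical parameter of the
#' small-angle RFT efficiency curve, K = C_perp/C_par, to a table of
#' (angle of attack, efficiency) bout measurements:
#' minimises sum_i (efficiency_i - eta(theta_a_i; K))^2 over K >= 1
#' (unweighted, as the bouts are exchangeable measurements). Uncertainty is
#' estimated by a nonparametric bootstrap over bouts.
#'
#' @param bouts data.frame with columns \code{theta_a} (degrees) and
#'   \code{efficiency}, one row per forward-locomotion bout.
#' @param theta_cap bouts with theta_a above this cap (degrees) are excluded
#'   from the fit (small-angle validity).
#' @param n_boot bootstrap resamples for the standard error (0 disables).
#' @param K_max upper bound of the search interval.
#' @param seed seed for the bootstrap resampling.
#' @return an object of class \code{rft_fit} with components \code{K},
#'   \code{C_ratio}, \code{residual} (sum of squared efficiency residuals),
#'   \code{n_bouts}, \code{boot_se}, \code{boot_ci}, \code{boundary},
#'   \code{data} and \code{call}.
#' @seealso \code{\link{rft_efficiency}}, \code{\link{make_rft_bouts}}
#' @export
fit_drag_ratio <- function(bouts, theta_cap = 60, n_boot = 1000,
                           K_max = 20, seed = NULL) {
  if (!all(c("theta_a", "efficiency") %in% names(bouts)))
    stop("bouts must have columns 'theta_a' and 'efficiency'")
  d <- bouts[is.finite(bouts$theta_a) & is.finite(bouts$efficiency) &
               bouts$theta_a <= theta_cap, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 bouts within the small-angle cap")
  sse <- function(K, dd) sum((dd$efficiency - rft_efficiency(dd$theta_a, K))^2)
  fit1 <- function(dd) {
    opt <- stats::optimize(sse, interval = c(1, K_max), dd = dd, tol = 1e-9)
    # optimize never quite reaches the interval ends; snap to the K = 1
    # boundary when it is at least as good
    if (sse(1, dd) <= opt$objective + 1e-15) list(K = 1, obj = sse(1, dd))
    else list(K = opt$minimum, obj = opt$objective)
  }
  est <- fit1(d)
  boundary <- est$K <= 1 + 1e-6
  if (boundary)
    warning("drag-ratio estimate at the K = 1 boundary (no measurable propulsion anisotropy)")
  boot_se <- NA_real_; boot_ci <- c(NA_real_, NA_real_); boot_K <- NULL
  if (n_boot > 0 && nrow(d) >= 3) {
    boot_K <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(d), replace = TRUE)
      fit1(d[idx, , drop = FALSE])$K
    }, 1))
    boot_se <- stats::sd(boot_K)
    boot_ci <- stats::quantile(boot_K, c(0.025, 0.975), names = FALSE)
  }
  structure(list(K = est$K, C_ratio = c(C_perp_over_C_par = est$K),
                 residual = est$obj, n_bouts = nrow(d),
                 n_excluded = nrow(bouts) - nrow(d),
                 boot_se = boot_se, boot_ci = boot_ci, n_boot = n_boot,
                 boundary = boundary, theta_cap = theta_cap,
                 data = d, call = match.call()),
            class = "rft_fit")
}

#' @export
print.rft_fit <- function(x, digits = 4, ...) {
  cat("Resistive-force-theory drag-ratio fit\n")
  cat(sprintf("  C_perp/C_par = %s", format(x$K, digits = digits)))
  if (is.finite(x$boot_se))
    cat(sprintf("  (bootstrap SE %s)", format(x$boot_se, digits = 3)))
  cat("\n")
  cat(sprintf("  %d bouts (%d excluded above %g deg), residual SS = %s\n",
              x$n_bouts, x$n_excluded, x$theta_cap,
              format(x$residual, digits = 3)))
  if (x$boundary)
    cat("  note: estimate at the isotropic-drag boundary K = 1\n")
  invisible(x)
}

#' @export
coef.rft_fit <- function(object, ...) c(K = object$K)

#' @export
fitted.rft_fit <- function(object, ...)
  rft_efficiency(object$data$theta_a, object$K)

#' @export
residuals.rft_fit <- function(object, ...)
  object$data$efficiency - fitted(object)

#' Predict efficiency from a fitted RFT model
#'
#' @param object an \code{rft_fit}.
#' @param newdata data.frame with a \code{theta_a} column (degrees), or a
#'   numeric vector of angles; defaults to the fitted data.
#' @param ... unused.
#' @return predicted efficiencies.
#' @export
predict.rft_fit <- function(object, newdata = NULL, ...) {
  theta <- if (is.null(newdata)) object$data$theta_a
  else if (is.numeric(newdata)) newdata else newdata$theta_a
  rft_efficiency(theta, object$K)
}

#' @export
summary.rft_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object, resid_sd = stats::sd(r),
                 resid_range = range(r)), class = "summary.rft_fit")
}

#' @export
print.summary.rft_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd %.4g, range [%.4g, %.4g]\n",
              x$resid_sd, x$resid_range[1], x$resid_range[2]))
  if (all(is.finite(x$fit$boot_ci)))
    cat(sprintf("  bootstrap 95%% CI [%.4g, %.4g] (%d resamples)\n",
                x$fit$boot_ci[1], x$fit$boot_ci[2], x$fit$n_boot))
  invisible(x)
}

#' Plot a fitted RFT efficiency curve over the bout data
#'
#' @param x an \code{rft_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.rft_fit <- function(x, ...) {
  d <- x$data
  plot(d$theta_a, d$efficiency, pch = 16, col = grDevices::grey(0.4),
       xlab = expression("angle of attack" ~ theta[a] ~ "(deg)"),
       ylab = expression("propulsion efficiency" ~ V[a] / V[w]), ...)
  th <- seq(0, max(d$theta_a), length.out = 200)
  graphics::lines(th, rft_efficiency(th, x$K), col = "magenta", lwd = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "C_perp/C_par = %.3g", x$K), lty = 1, col = "magenta", lwd = 2)
  invisible(x)
}

#' Simulate bout tables from a fitted RFT model
#'
#' Draws new (theta_a, efficiency) tables from the fitted curve with
#' Gaussian noise at the residual standard deviation, matching the observed
#' angle range and bout count.
#'
#' @param object an \code{rft_fit}.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of data.frames (a single data.frame when \code{nsim = 1}).
#' @export
simulate.rft_fit <- function(object, nsim = 1, seed = 1L, ...) {
  sdr <- stats::sd(residuals(object))
  rng <- range(object$data$theta_a)
  sims <- lapply(seq_len(nsim), function(i)
    make_rft_bouts(object$K, n_bouts = object$n_bouts, theta_range = rng,
                   efficiency_noise_sd = sdr, seed = seed + i - 1L))
  if (nsim == 1) sims[[1]] else sims
}
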