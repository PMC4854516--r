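# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
# All synthetic generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Unwrap a sequence of angles (radians) so successive differences lie in (-pi, pi].
unwrap <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta[1] + c(0, cumsum(d))
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_config(field, "must be a single positive finite number")
  invisible(x)
}

# Convert mask (row, col) pixel indices to mm coordinates with y increasing upward.
px_to_mm <- function(rowcol, nrow_img, mm_per_px) {
  cbind(x = (rowcol[, 2] - 0.5) * mm_per_px,
        y = (nrow_img - rowcol[, 1] + 0.5) * mm_per_px)
}

# Population standard deviation (divide by N).
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}
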