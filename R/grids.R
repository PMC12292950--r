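#' Uniform time grid
#'
#' A uniform time grid with points `t_k = t0 + k * dt`, `k = 0, ..., n_steps`.
#' All discrete fractional operators in this package assume such a grid: the
#' L1 weights are only valid for constant step size.
#'
#' @param t0 Time origin (s).
#' @param dt Step size (s), strictly positive.
#' @param n_steps Number of steps (the grid holds `n_steps + 1` points).
#' @return An object of class `"time_grid"`.
#' @examples
#' g <- time_grid(0, 0.1, 10)
#' grid_times(g)
#' @export
time_grid <- function(t0 = 0, dt, n_steps) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L)
    stop("`n_steps` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number", call. = FALSE)
  structure(list(t0 = t0, dt = dt, n_steps = n_steps), class = "time_grid")
}

#' @rdname time_grid
#' @param grid A `time_grid`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + (0:grid$n_steps) * grid$dt
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> t0 = %g, dt = %g, n_steps = %d (t in [%g, %g])\n",
              x$t0, x$dt, x$n_steps, x$t0, x$t0 + x$n_steps * x$dt))
  invisible(x)
}

#' Scalar time series on a uniform grid
#'
#' Holds samples `f(t_k)` together with the population standard deviation of
#' the samples, which the loss functions use as a scale. A zero standard
#' deviation is allowed at construction but rejected wherever it would appear
#' as a loss denominator.
#'
#' @param values Numeric vector of length `n_steps + 1`.
#' @param grid A [time_grid()].
#' @param sigma Optional scale; defaults to the population standard deviation
#'   of `values`.
#' @return An object of class `"scalar_series"`.
#' @export
scalar_series <- function(values, grid, sigma = NULL) {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_steps + 1L)
    stop(sprintf("`values` must have length n_steps + 1 = %d, got %d",
                 grid$n_steps + 1L, length(values)), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (is.null(sigma)) sigma <- pop_sd(values)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  structure(list(grid = grid, values = values, sigma = sigma),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> %d samples, dt = %g, sigma = %.4g\n",
              length(x$values), x$grid$dt, x$sigma))
  invisible(x)
}

# population standard deviation (denominator n, not n - 1)
pop_sd <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

# validate a fractional order in [0, 1]
check_order <- function(alpha, name = "alpha") {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (alpha < 0 || alpha > 1)
    stop(sprintf("`%s` must lie in [0, 1], got %g", name, alpha),
         call. = FALSE)
  alpha
}
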