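#' Benchmark scenario for the time-fractional diffusion equation
#'
#' Describes one forward problem
#' \deqn{\partial^\alpha c/\partial t^\alpha =
#'   \tilde D(c)(c_{xx}+c_{yy}) + \tilde D_c(c)(c_x^2+c_y^2) + f}
#' on a rectangle with fixed-value (Dirichlet) boundaries. The default is the
#' package's synthetic benchmark: unit square, 48 x 48 spatial grid, 40 time
#' steps to `t = 1`, Gaussian bump initial condition
#' `exp(-((x-1/2)^2 + (y-1/2)^2) / 0.05)`, homogeneous Dirichlet boundary, and
#' the concentration-dependent law `D(c) = 0.1 (1 + c^2)`.
#'
#' @param alpha True fractional order in `[0, 1]`.
#' @param law A [diffusion_law()].
#' @param xlim,ylim Domain bounds (length units).
#' @param nx,ny Number of grid points per axis (including boundaries), `>= 8`.
#' @param t_max Final time (s).
#' @param n_steps Number of time steps.
#' @param ic Initial condition, a function `(x, y) -> c`.
#' @param bc_value Constant Dirichlet boundary value.
#' @param source Optional source term `f(t, x, y)` (vectorized in `x`, `y`),
#'   mainly for manufactured-solution verification.
#' @return An object of class `"diffusion_scenario"`.
#' @export
diffusion_scenario <- function(alpha = 0.5,
                               law = default_diffusion_law(),
                               xlim = c(0, 1), ylim = c(0, 1),
                               nx = 48L, ny = 48L,
                               t_max = 1, n_steps = 40L,
                               ic = function(x, y)
                                 exp(-((x - 0.5)^2 + (y - 0.5)^2) / 0.05),
                               bc_value = 0,
                               source = NULL) {
  check_order(alpha)
  stopifnot(inherits(law, "diffusion_law"), is.function(ic))
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L) stop("`nx` and `ny` must be >= 8", call. = FALSE)
  if (t_max <= 0) stop("`t_max` must be positive", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("`n_steps` must be >= 1", call. = FALSE)
  grid <- time_grid(0, t_max / n_steps, n_steps)
  structure(list(alpha = alpha, law = law, xlim = xlim, ylim = ylim,
                 nx = nx, ny = ny, grid = grid, ic = ic,
                 bc_value = bc_value, source = source),
            class = "diffusion_scenario")
}

#' Spatio-temporal concentration field
#'
#' Container for concentration samples on the uniform `(t, x, y)` tensor grid,
#' together with the population standard deviation of all samples (the scale
#' used by the variance-scaled losses).
#'
#' @param values Array of dimension `(n_steps + 1, nx, ny)`.
#' @param grid A [time_grid()].
#' @param x,y Uniform spatial coordinate vectors.
#' @param scenario Optional generating [diffusion_scenario()] (kept as truth
#'   reference for error reporting).
#' @return An object of class `"st_field"`.
#' @export
st_field <- function(values, grid, x, y, scenario = NULL) {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.array(values)
  d <- dim(values)
  if (length(d) != 3L || d[1] != grid$n_steps + 1L || d[2] != length(x) ||
      d[3] != length(y))
    stop("`values` must be an (n_steps + 1, nx, ny) array matching the grids",
         call. = FALSE)
  if (length(x) > 2 && diff(range(diff(x))) > 1e-9 * abs(diff(range(x))))
    stop("`x` must be uniform", call. = FALSE)
  if (length(y) > 2 && diff(range(diff(y))) > 1e-9 * abs(diff(range(y))))
    stop("`y` must be uniform", call. = FALSE)
  structure(list(grid = grid, x = as.numeric(x), y = as.numeric(y),
                 values = values, sigma_c = pop_sd(values),
                 scenario = scenario),
            class = "st_field")
}

#' @export
print.st_field <- function(x, ...) {
  cat(sprintf("<st_field> %d x %d x %d (t, x, y), sigma_c = %.4g\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$sigma_c))
  invisible(x)
}

#' Keep every k-th spatial point of a field
#'
#' Thins a dense simulated field to a sparser observation grid (stride per
#' axis), emulating measurements that sample the domain more coarsely than the
#' solver resolves it. Time resolution is kept: the L1 stencil wants the full
#' history.
#'
#' @param field An [st_field()].
#' @param stride Integer stride `>= 1` applied to both spatial axes.
#' @return An [st_field()] on the thinned grid.
#' @export
thin_field <- function(field, stride = 2L) {
  stopifnot(inherits(field, "st_field"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("`stride` must be >= 1", call. = FALSE)
  ix <- seq(1L, length(field$x), by = stride)
  iy <- seq(1L, length(field$y), by = stride)
  st_field(field$values[, ix, iy, drop = FALSE], field$grid,
           field$x[ix], field$y[iy], scenario = field$scenario)
}

#' Solve the time-fractional diffusion equation
#'
#' Implicit L1 time stepping for the forward problem: at each step the scheme
#' solves
#' \deqn{c^{k+1} - \Gamma(2-\alpha)\Delta t^\alpha\, g(c^{k+1}) = h_k (+ f)}
#' with second-order central differences in space and Picard iteration on the
#' lagged nonlinearity (coefficients \eqn{\tilde D, \tilde D_c} and the
#' gradient-squared term frozen at the previous iterate) until the update
#' max-norm falls below `picard_tol` or `picard_max` sweeps are exhausted.
#' The implicit treatment is unconditionally stable for the stiff Laplacian.
#'
#' Temporal accuracy is the L1 scheme's order \eqn{2-\alpha} (first order at
#' \eqn{\alpha = 1}, where the scheme reduces to backward Euler), spatial
#' accuracy is second order.
#'
#' @param scenario A [diffusion_scenario()].
#' @param picard_tol Convergence tolerance on the Picard update (max-norm).
#' @param picard_max Maximum Picard sweeps per step.
#' @return An [st_field()] with the scenario attached.
#' @export
solve_tfde <- function(scenario, picard_tol = 1e-10, picard_max = 50L) {
  stopifnot(inherits(scenario, "diffusion_scenario"))
  sc <- scenario
  nx <- sc$nx; ny <- sc$ny
  xs <- seq(sc$xlim[1], sc$xlim[2], length.out = nx)
  ys <- seq(sc$ylim[1], sc$ylim[2], length.out = ny)
  hx <- xs[2] - xs[1]; hy <- ys[2] - ys[1]
  n <- sc$grid$n_steps; dt <- sc$grid$dt
  alpha <- sc$alpha
  pref <- gamma(2 - alpha) * dt^alpha
  b <- l1_weights(alpha, n)

  # interior indexing (Dirichlet boundary held at bc_value)
  ixi <- 2:(nx - 1L); iyi <- 2:(ny - 1L)
  nxi <- nx - 2L; nyi <- ny - 2L
  nint <- nxi * nyi
  XI <- matrix(rep(xs[ixi], nyi), nxi, nyi)
  YI <- matrix(rep(ys[iyi], each = nxi), nxi, nyi)

  # sparse 5-point Laplacian on interior unknowns + boundary contribution
  id <- matrix(seq_len(nint), nxi, nyi)
  trip_i <- c(); trip_j <- c(); trip_v <- c()
  addt <- function(i, j, v) {
    trip_i <<- c(trip_i, i); trip_j <<- c(trip_j, j); trip_v <<- c(trip_v, v)
  }
  addt(as.vector(id), as.vector(id), rep(-2 / hx^2 - 2 / hy^2, nint))
  addt(as.vector(id[-1, ]), as.vector(id[-nxi, ]), rep(1 / hx^2, (nxi - 1) * nyi))
  addt(as.vector(id[-nxi, ]), as.vector(id[-1, ]), rep(1 / hx^2, (nxi - 1) * nyi))
  addt(as.vector(id[, -1]), as.vector(id[, -nyi]), rep(1 / hy^2, nxi * (nyi - 1)))
  addt(as.vector(id[, -nyi]), as.vector(id[, -1]), rep(1 / hy^2, nxi * (nyi - 1)))
  Lap <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_v,
                              dims = c(nint, nint))
  bvec <- numeric(nint)
  g0 <- sc$bc_value
  bvec[id[1, ]] <- bvec[id[1, ]] + g0 / hx^2
  bvec[id[nxi, ]] <- bvec[id[nxi, ]] + g0 / hx^2
  bvec[id[, 1]] <- bvec[id[, 1]] + g0 / hy^2
  bvec[id[, nyi]] <- bvec[id[, nyi]] + g0 / hy^2

  # central first/second differences of the full field at interior points
  full <- function(ci) {
    cf <- matrix(g0, nx, ny)
    cf[ixi, iyi] <- matrix(ci, nxi, nyi)
    cf
  }
  grad_sq <- function(cf) {
    gx <- (cf[3:nx, iyi] - cf[1:(nx - 2L), iyi]) / (2 * hx)
    gy <- (cf[ixi, 3:ny] - cf[ixi, 1:(ny - 2L)]) / (2 * hy)
    as.vector(gx^2 + gy^2)
  }

  cstore <- matrix(0, nint, n + 1L)
  cstore[, 1] <- as.vector(sc$ic(XI, YI))
  const_d <- attr(sc$law, "constant")
  Afac <- NULL
  if (!is.null(const_d)) {
    A <- Matrix::Diagonal(nint) - pref * const_d * Lap
    Afac <- Matrix::Cholesky(Matrix::forceSymmetric(A))
  }

  only_b0 <- alpha == 1
  for (k in 0:(n - 1L)) {
    # history term h_k = c_k + sum_{j=1..k} b_j (c_{k-j} - c_{k+1-j})
    h <- cstore[, k + 1L]
    if (!only_b0 && k >= 1L) {
      dmat <- cstore[, 1:k, drop = FALSE] - cstore[, 2:(k + 1L), drop = FALSE]
      h <- h + as.vector(dmat[, k:1, drop = FALSE] %*% b[2:(k + 1L)])
    }
    src <- 0
    if (!is.null(sc$source)) {
      tk1 <- sc$grid$t0 + (k + 1L) * dt
      src <- as.vector(sc$source(tk1, XI, YI))
    }
    cur <- cstore[, k + 1L]
    conv <- FALSE
    for (it in seq_len(picard_max)) {
      dv <- sc$law$dcoef(cur)
      if (any(dv <= 0))
        stop("solve_tfde: non-positive diffusion coefficient encountered",
             call. = FALSE)
      dcv <- sc$law$dcoef_deriv(cur)
      rhs <- h + pref * (dv * bvec + dcv * grad_sq(full(cur)) + src)
      if (!is.null(Afac)) {
        nxt <- as.numeric(Matrix::solve(Afac, rhs))
      } else {
        A <- Matrix::Diagonal(nint) - pref * Matrix::Diagonal(x = dv) %*% Lap
        nxt <- as.numeric(Matrix::solve(A, rhs))
      }
      if (max(abs(nxt - cur)) < picard_tol) { cur <- nxt; conv <- TRUE; break }
      cur <- nxt
    }
    if (!conv)
      stop(sprintf("solve_tfde: Picard iteration did not converge at step %d",
                   k + 1L), call. = FALSE)
    cstore[, k + 2L] <- cur
  }

  vals <- array(g0, dim = c(n + 1L, nx, ny))
  for (k in 0:n) {
    cf <- full(cstore[, k + 1L])
    vals[k + 1L, , ] <- cf
  }
  st_field(vals, sc$grid, xs, ys, scenario = sc)
}
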