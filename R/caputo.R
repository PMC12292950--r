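#' L1 weights for the Caputo derivative
#'
#' Computes the coefficient sequence \eqn{b_j = (j+1)^{1-\alpha} - j^{1-\alpha}}
#' of the L1 finite-difference scheme for the Caputo derivative of order
#' \eqn{\alpha \in [0, 1]}. The endpoints are exact limits: for \eqn{\alpha = 1}
#' the weights are \eqn{(1, 0, 0, \dots)} (backward difference), for
#' \eqn{\alpha = 0} they are all one (difference from the initial value).
#'
#' Properties used throughout: \eqn{b_0 = 1} for every order; for
#' \eqn{0 < \alpha < 1} the weights are positive and strictly decreasing; and
#' \eqn{\sum_{j=0}^{K} b_j = (K+1)^{1-\alpha}} (telescoping).
#'
#' @param alpha Fractional order in `[0, 1]`.
#' @param K Largest index; the result holds `b_0, ..., b_K`.
#' @param dt Optional step size stored alongside the weights.
#' @return An object of class `"caputo_weights"` with fields `order`,
#'   `coefficients` (length `K + 1`) and `dt`.
#' @examples
#' caputo_weights(0.5, 3)$coefficients
#' @export
caputo_weights <- function(alpha, K, dt = NA_real_) {
  check_order(alpha)
  K <- as.integer(K)
  if (is.na(K) || K < 0L) stop("`K` must be an integer >= 0", call. = FALSE)
  b <- l1_weights(alpha, K)
  structure(list(order = alpha, coefficients = b, dt = dt),
            class = "caputo_weights")
}

# bare numeric L1 weights b_0..b_K
l1_weights <- function(alpha, K) {
  if (alpha == 1) return(c(1, rep(0, K)))
  j <- 0:K
  (j + 1)^(1 - alpha) - j^(1 - alpha)
}

# d b_j / d alpha, for alpha in (0, 1) (used by the trainable operators)
l1_weights_dalpha <- function(alpha, K) {
  j <- 0:K
  d <- -(j + 1)^(1 - alpha) * log(j + 1)
  jj <- j[j > 0]
  d[j > 0] <- d[j > 0] + jj^(1 - alpha) * log(jj)
  d
}

#' Discrete Caputo derivative (L1 scheme)
#'
#' Applies the L1 finite-difference approximation of the Caputo derivative of
#' order `alpha` to a series on a uniform grid:
#' \deqn{L^\alpha_t f(t_{k+1}) = \frac{1}{\Gamma(2-\alpha)\,\Delta t^\alpha}
#'   \sum_{j=0}^{k} b_j\,[f(t_{k+1-j}) - f(t_{k-j})].}
#' The scheme is exact for piecewise-linear `f` and has accuracy order
#' \eqn{2 - \alpha} for smooth `f`. At \eqn{\alpha = 1} it reduces exactly to
#' the backward difference, at \eqn{\alpha = 0} to \eqn{f(t_{k+1}) - f(t_0)}.
#'
#' @param f A [scalar_series()] (at least 3 samples).
#' @param alpha Fractional order in `[0, 1]`.
#' @return A [scalar_series()] holding the derivative at `t_1, ..., t_n`
#'   (one sample fewer than the input, on the grid shifted by one step).
#' @export
caputo_l1 <- function(f, alpha) {
  stopifnot(inherits(f, "scalar_series"))
  check_order(alpha)
  n <- f$grid$n_steps
  if (n < 2L)
    stop("`f` must have at least 3 samples on a uniform grid", call. = FALSE)
  W <- caputo_l1_matrix(alpha, n, f$grid$dt)
  out <- as.numeric(W %*% f$values)
  scalar_series(out, time_grid(f$grid$t0 + f$grid$dt, f$grid$dt, n - 1L))
}

#' L1 operator matrix
#'
#' The dense matrix `W` (`n` rows, `n + 1` columns) with
#' `(W %*% f)[k] = L1 Caputo derivative of f at t_k`, `k = 1..n`, including the
#' `1 / (Gamma(2 - alpha) dt^alpha)` prefactor.
#'
#' @param alpha Fractional order in `[0, 1]`.
#' @param n Number of output samples (input has `n + 1`).
#' @param dt Step size.
#' @export
caputo_l1_matrix <- function(alpha, n, dt) {
  check_order(alpha)
  b <- l1_weights(alpha, n - 1L)
  pref <- 1 / (gamma(2 - alpha) * dt^alpha)
  l1_diff_matrix(b, n) * pref
}

#' History term of the L1 scheme
#'
#' The regrouped history term
#' \deqn{h(c, t_k) = b_0 c(t_k) - \sum_{j=0}^{k-1} b_{j+1} c(t_{k-j})
#'   + \sum_{j=1}^{k} b_j c(t_{k-j}),}
#' which collects everything the L1 stencil at \eqn{t_{k+1}} knows about the
#' past. It satisfies the identity
#' \eqn{c(t_{k+1}) = \Gamma(2-\alpha)\Delta t^\alpha\, L^\alpha_t c(t_{k+1}) + h(c, t_k)},
#' which is the basis of the physics-informed reconstruction. For `k = 0` both
#' sums are empty and `h = c(t_0)`; for `alpha = 1`, `h = c(t_k)`.
#'
#' @param c A [scalar_series()].
#' @param alpha Fractional order in `[0, 1]`.
#' @param k Time index, `0 <= k <= n_steps - 1` (zero-based).
#' @return The scalar `h(c, t_k)`.
#' @export
history_term <- function(c, alpha, k) {
  stopifnot(inherits(c, "scalar_series"))
  check_order(alpha)
  k <- as.integer(k)
  n <- c$grid$n_steps
  if (is.na(k) || k < 0L || k > n - 1L)
    stop(sprintf("`k` must lie in [0, %d], got %d", n - 1L, k), call. = FALSE)
  b <- l1_weights(alpha, k)
  v <- c$values                       # v[i + 1] = c(t_i)
  h <- b[1] * v[k + 1L]
  if (k >= 1L) {
    j1 <- 0:(k - 1L)
    h <- h - sum(b[j1 + 2L] * v[k - j1 + 1L])
    j2 <- 1:k
    h <- h + sum(b[j2 + 1L] * v[k - j2 + 1L])
  }
  h
}

#' History operator matrix
#'
#' Dense matrix `H` (`n` rows, `n + 1` columns) with
#' `(H %*% c)[r] = h(c, t_{r-1})`, so that row `r` produces the history term
#' entering the reconstruction of `c(t_r)`.
#'
#' @inheritParams caputo_l1_matrix
#' @export
history_matrix <- function(alpha, n) {
  check_order(alpha)
  b <- l1_weights(alpha, n)
  history_matrix_from_b(b, n)
}

# vectorized fill: row r holds b_0 at column r, +b_{r-c} at columns c < r and
# -b_{r-c+1} at columns 2..r; fill indices cached per size (rebuilt every
# training iteration)
history_matrix_from_b <- function(b, n) {
  key <- paste0("hist_", n)
  ix <- .op_cache[[key]]
  if (is.null(ix)) {
    ro <- .row(c(n, n + 1L)); co <- .col(c(n, n + 1L))
    s1 <- which(co <= ro - 1L)
    s2 <- which(co >= 2L & co <= ro)
    ix <- list(i1 = s1, b1 = (ro - co + 1L)[s1],
               i2 = s2, b2 = (ro - co + 2L)[s2],
               id = seq_len(n) + (seq_len(n) - 1L) * n)
    .op_cache[[key]] <- ix
  }
  H <- numeric(n * (n + 1L))
  H[ix$i1] <- b[ix$b1]
  H[ix$i2] <- H[ix$i2] - b[ix$b2]
  H[ix$id] <- H[ix$id] + b[1]
  dim(H) <- c(n, n + 1L)
  H
}
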