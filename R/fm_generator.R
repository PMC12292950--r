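#' Paired stress-strain series
#'
#' Stress \eqn{\tau(t)} (Pa) and strain \eqn{\epsilon(t)} (dimensionless) on a
#' shared uniform time grid, as produced by a stress-relaxation experiment or
#' by [generate_fm_dataset()].
#'
#' @param stress,strain Numeric vectors of length `n_steps + 1` (or
#'   [scalar_series()] objects on `grid`).
#' @param grid A [time_grid()].
#' @param eps0 Applied step strain, if applicable.
#' @return An object of class `"stress_strain_series"`.
#' @export
stress_strain_series <- function(stress, strain, grid, eps0 = NA_real_) {
  if (inherits(stress, "scalar_series")) stress <- stress$values
  if (inherits(strain, "scalar_series")) strain <- strain$values
  structure(list(grid = grid,
                 stress = scalar_series(stress, grid),
                 strain = scalar_series(strain, grid),
                 eps0 = eps0),
            class = "stress_strain_series")
}

#' @export
print.stress_strain_series <- function(x, ...) {
  cat(sprintf("<stress_strain_series> %d samples, dt = %g s, sigma_tau = %.4g Pa, sigma_eps = %.4g\n",
              length(x$stress$values), x$grid$dt, x$stress$sigma,
              x$strain$sigma))
  invisible(x)
}

# smooth 0 -> 1 ramp profile, exactly 0 at u = 0 and 1 at u = 1
ramp_profile <- function(u) {
  (tanh(4 * (2 * u - 1)) + tanh(4)) / (2 * tanh(4))
}

#' Synthetic fractional Maxwell stress-relaxation dataset
#'
#' Emulates a step-strain relaxation experiment: the strain rises smoothly
#' (tanh profile) to `eps0` over the first `ramp_steps` grid intervals and is
#' held constant afterwards. A true step would have an unbounded L1
#' derivative; real rheometers also apply a fast-but-finite rise. The stress
#' is obtained by integrating the constitutive law with the L1 scheme step by
#' step over the whole horizon (each update is linear in the unknown stress),
#' so the generated pair satisfies the discrete law exactly — the
#' self-consistency the inverse solver relies on. After the ramp the stress
#' converges to the closed form \eqn{\tau(t) = G(t)\epsilon_0}
#' ([relaxation_modulus()]) as the step size shrinks; substituting the closed
#' form directly would instead leave an O(1) law violation at the
#' ramp/closed-form junction, because the closed form assumes an ideal step at
#' `t = 0`.
#'
#' @param p An [fm_params()] object (the ground truth).
#' @param eps0 Step strain, dimensionless.
#' @param grid A [time_grid()]; default 200 steps of 0.05 s.
#' @param ramp_steps Grid intervals used by the strain ramp (default 5).
#' @return A [stress_strain_series()] with the truth attached as attribute
#'   `"truth"`.
#' @export
generate_fm_dataset <- function(p, eps0 = 1,
                                grid = time_grid(0, 0.05, 200L),
                                ramp_steps = 5L) {
  stopifnot(inherits(p, "fm_params"), inherits(grid, "time_grid"))
  ramp_steps <- as.integer(ramp_steps)
  n <- grid$n_steps
  if (ramp_steps < 1L || ramp_steps >= n)
    stop("`ramp_steps` must be in [1, n_steps - 1]", call. = FALSE)
  dt <- grid$dt
  tt <- grid_times(grid)

  k_idx <- 0:n
  strain <- ifelse(k_idx >= ramp_steps, eps0,
                   eps0 * ramp_profile(k_idx / ramp_steps))

  stress <- numeric(n + 1L)
  if (eps0 != 0) {
    b_nu <- l1_weights(p$nu, n)
    b_mu <- l1_weights(p$mu, n)
    pref_nu <- gamma(2 - p$nu) * dt^p$nu
    pref_mu <- gamma(2 - p$mu) * dt^p$mu
    q <- p$eta / pref_mu
    for (k in 0:(n - 1L)) {
      # L1 strain derivative at t_{k+1}
      jj <- 0:k
      dstr <- sum(b_nu[jj + 1L] * (strain[k + 2L - jj] - strain[k + 1L - jj])) /
        pref_nu
      # history of the stress at t_k
      h <- stress[k + 1L]
      if (k >= 1L) {
        j2 <- 1:k
        h <- h + sum(b_mu[j2 + 1L] *
                       (stress[k + 1L - j2] - stress[k + 2L - j2]))
      }
      stress[k + 2L] <- (p$kappa * dstr + q * h) / (1 + q)
    }
  }

  out <- stress_strain_series(stress, strain, grid, eps0 = eps0)
  attr(out, "truth") <- p
  out
}
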