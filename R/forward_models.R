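#' Concentration-dependent diffusion law
#'
#' Couples a generalized diffusion coefficient \eqn{\tilde D(c)} (units
#' length\eqn{^2}/time\eqn{^\alpha}) with its analytic derivative
#' \eqn{\tilde D_c(c) = d\tilde D/dc}. Both enter the nonlinear right-hand
#' side \eqn{g = \tilde D\,(c_{xx}+c_{yy}) + \tilde D_c\,(c_x^2+c_y^2)}, the
#' chain-rule expansion of \eqn{\nabla\cdot(\tilde D(c)\nabla c)}.
#'
#' @param dcoef Function `c -> D(c)`, positive over the range of interest.
#' @param dcoef_deriv Function `c -> dD/dc`, the analytic derivative.
#' @param label Optional human-readable description (kept in metadata).
#' @return An object of class `"diffusion_law"`.
#' @seealso [default_diffusion_law()], [constant_diffusion_law()]
#' @export
diffusion_law <- function(dcoef, dcoef_deriv, label = "custom") {
  stopifnot(is.function(dcoef), is.function(dcoef_deriv))
  structure(list(dcoef = dcoef, dcoef_deriv = dcoef_deriv, label = label),
            class = "diffusion_law")
}

#' @describeIn diffusion_law The benchmark law
#'   \eqn{\tilde D(c) = D_0 (1 + c^2)} (smooth, positive, genuinely
#'   concentration-dependent), default \eqn{D_0 = 0.1}.
#' @param d0 Base coefficient \eqn{D_0}.
#' @export
default_diffusion_law <- function(d0 = 0.1) {
  force(d0)
  diffusion_law(function(c) d0 * (1 + c^2),
                function(c) 2 * d0 * c,
                label = sprintf("%g*(1+c^2)", d0))
}

#' @describeIn diffusion_law A constant law \eqn{\tilde D(c) = D_0}
#'   (reduces the model to linear sub-diffusion).
#' @export
constant_diffusion_law <- function(d0 = 0.1) {
  force(d0)
  law <- diffusion_law(function(c) rep(d0, length(c)),
                       function(c) rep(0, length(c)),
                       label = sprintf("constant %g", d0))
  attr(law, "constant") <- d0
  law
}

#' Point values of a field and its spatial derivatives
#'
#' @param c Concentration.
#' @param cx,cy First spatial partial derivatives.
#' @param cxx,cyy Second spatial partial derivatives.
#' @return An object of class `"field_derivatives"` (all fields vectorized).
#' @export
field_derivatives <- function(c, cx, cy, cxx, cyy) {
  vals <- list(c = c, cx = cx, cy = cy, cxx = cxx, cyy = cyy)
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L)
    stop("all derivative components must have the same length", call. = FALSE)
  if (any(!vapply(vals, function(v) all(is.finite(v)), logical(1))))
    stop("derivative components must be finite", call. = FALSE)
  structure(vals, class = "field_derivatives")
}

#' Right-hand side of the nonlinear time-fractional diffusion equation
#'
#' Evaluates \eqn{g(c, D) = \tilde D(c)(c_{xx} + c_{yy}) +
#' \tilde D_c(c)(c_x^2 + c_y^2)}, the divergence-form diffusion term expanded
#' by the chain rule for a concentration-dependent coefficient.
#'
#' @param d A [field_derivatives()] object.
#' @param law A [diffusion_law()].
#' @return Numeric vector `g`, one value per point.
#' @export
diffusion_rhs <- function(d, law) {
  stopifnot(inherits(d, "field_derivatives"), inherits(law, "diffusion_law"))
  law$dcoef(d$c) * (d$cxx + d$cyy) + law$dcoef_deriv(d$c) * (d$cx^2 + d$cy^2)
}

#' Fractional Maxwell parameters
#'
#' The four parameters of the fractional Maxwell constitutive law
#' \deqn{\tau(t) + \eta\, \frac{d^\mu \tau}{dt^\mu} =
#'       \kappa\, \frac{d^\nu \epsilon}{dt^\nu},}
#' with `kappa` in Pa s\eqn{^\nu} and `eta` in s\eqn{^\mu} (the placement of
#' `eta` on the stress derivative follows the constitutive law as used here;
#' parameter values are not directly comparable to other fractional-Maxwell
#' conventions). By default the order constraint \eqn{0 \le \nu \le \mu \le 1}
#' is enforced; set `enforce_order = FALSE` to allow \eqn{\nu > \mu}.
#'
#' @param kappa Springpot firmness, `> 0` (Pa s^nu).
#' @param eta Ratio parameter, `> 0` (s^mu).
#' @param mu Order of the stress derivative, in `[0, 1]`.
#' @param nu Order of the strain derivative, in `[0, 1]`.
#' @param enforce_order Require `nu <= mu` (default `TRUE`).
#' @return An object of class `"fm_params"`.
#' @export
fm_params <- function(kappa, eta, mu, nu, enforce_order = TRUE) {
  for (nm in c("kappa", "eta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  check_order(mu, "mu"); check_order(nu, "nu")
  if (enforce_order && nu > mu)
    stop(sprintf("order constraint violated: nu = %g > mu = %g ", nu, mu),
         call. = FALSE)
  structure(list(kappa = kappa, eta = eta, mu = mu, nu = nu),
            class = "fm_params")
}

#' @export
print.fm_params <- function(x, ...) {
  cat(sprintf("<fm_params> kappa = %.4g Pa s^nu, eta = %.4g s^mu, mu = %.4g, nu = %.4g\n",
              x$kappa, x$eta, x$mu, x$nu))
  invisible(x)
}

#' Relaxation modulus of the fractional Maxwell model
#'
#' \deqn{G(t) = \frac{\kappa}{\eta}\, t^{\mu-\nu}\,
#'       E_{\mu,\,1+\mu-\nu}\!\left(-\frac{t^\mu}{\eta}\right)}
#' evaluated through [mittag_leffler()]. `t = 0` is accepted only when
#' `mu == nu` (there `G(0) = kappa / eta` exactly); otherwise evaluation grids
#' should start at `t = dt`.
#'
#' @param p An [fm_params()] object.
#' @param t Positive times (vectorized), seconds.
#' @return `G(t)` in Pa.
#' @export
relaxation_modulus <- function(p, t) {
  stopifnot(inherits(p, "fm_params"))
  t <- as.numeric(t)
  if (anyNA(t) || any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0", call. = FALSE)
  if (any(t == 0) && p$mu != p$nu)
    stop("t = 0 is only admissible when mu == nu; start the grid at t = dt",
         call. = FALSE)
  out <- numeric(length(t))
  pos <- t > 0
  out[!pos] <- p$kappa / p$eta                # mu == nu limit
  if (any(pos)) {
    tp <- t[pos]
    out[pos] <- (p$kappa / p$eta) * tp^(p$mu - p$nu) *
      mittag_leffler(p$mu, 1 + p$mu - p$nu, -tp^p$mu / p$eta)
  }
  out
}

#' Stress response to a step strain
#'
#' For an ideal step strain of size `eps0` applied at `t = 0`, the stress is
#' \eqn{\tau(t) = G(t)\,\epsilon_0} with `G` from [relaxation_modulus()].
#'
#' @param p An [fm_params()] object.
#' @param eps0 Step strain (dimensionless).
#' @param grid A [time_grid()]; must not contain `t = 0` unless `mu == nu`.
#' @return A [scalar_series()] of stresses (Pa).
#' @export
stress_step_strain <- function(p, eps0, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.numeric(eps0) || length(eps0) != 1L || !is.finite(eps0))
    stop("`eps0` must be a single finite number", call. = FALSE)
  tt <- grid_times(grid)
  if (eps0 == 0) return(scalar_series(rep(0, length(tt)), grid))
  scalar_series(relaxation_modulus(p, tt) * eps0, grid)
}

#' Physics-informed stress from the fractional Maxwell law
#'
#' Rearranges the constitutive law for the instantaneous stress and evaluates
#' it with the L1 operators:
#' \deqn{\tau^{pi}(t_{k+1}) = \kappa\, L^\nu_t \epsilon(t_{k+1})
#'       - \eta\, L^\mu_t \tau(t_{k+1}).}
#' When `strain` and `stress` jointly satisfy the fractional Maxwell law, the
#' result reproduces `stress` up to the L1 discretization error; the mismatch
#' is the consistency residual minimized by [fit_fractional_maxwell()].
#'
#' @param strain,stress [scalar_series()] on one shared uniform grid.
#' @param p An [fm_params()] object.
#' @return A [scalar_series()] holding \eqn{\tau^{pi}} at `t_1, ..., t_n`.
#' @export
fm_physics_stress <- function(strain, stress, p) {
  stopifnot(inherits(strain, "scalar_series"), inherits(stress, "scalar_series"),
            inherits(p, "fm_params"))
  g1 <- strain$grid; g2 <- stress$grid
  if (g1$n_steps != g2$n_steps || abs(g1$dt - g2$dt) > 1e-12 * g1$dt ||
      abs(g1$t0 - g2$t0) > 1e-12 * max(abs(g1$t0), g1$dt))
    stop("`strain` and `stress` must share one uniform grid", call. = FALSE)
  de <- caputo_l1(strain, p$nu)
  dt_ <- caputo_l1(stress, p$mu)
  scalar_series(p$kappa * de$values - p$eta * dt_$values, de$grid)
}
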