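#' Variance-scaled data loss for the diffusion problem
#'
#' \deqn{L_{data} = \mathrm{mean}\,|c^{pu} - c|^2 / \sigma_c^2,}
#' the mean squared misfit between surrogate predictions and reference
#' concentrations, scaled by the variance of the reference field so that the
#' loss is invariant under a change of concentration units.
#'
#' @param c_pred Predicted concentrations (any shape).
#' @param c_ref Reference: an [st_field()], or a numeric array with `sigma`
#'   supplied.
#' @param sigma Scale override; defaults to the reference field's `sigma_c`.
#' @return The dimensionless loss.
#' @export
data_loss_ad <- function(c_pred, c_ref, sigma = NULL) {
  if (inherits(c_ref, "st_field")) {
    sigma <- sigma %||% c_ref$sigma_c
    c_ref <- c_ref$values
  }
  if (is.null(sigma)) stop("`sigma` required for bare arrays", call. = FALSE)
  if (sigma <= 0)
    stop("sigma must be positive: a constant reference field cannot scale a loss",
         call. = FALSE)
  if (length(c_pred) != length(c_ref))
    stop("prediction/reference size mismatch", call. = FALSE)
  mean((as.numeric(c_pred) - as.numeric(c_ref))^2) / sigma^2
}

#' Consistency loss between physics-informed and surrogate fields
#'
#' \deqn{L_{consistency} = \mathrm{mean}\,|c^{pi} - c^{pu}|^2 / \sigma^2.}
#' The total training loss is the plain sum `data + consistency` with unit
#' weights.
#'
#' @param c_pi Physics-informed reconstruction.
#' @param c_pu Surrogate prediction at the same points.
#' @param sigma Reference-field standard deviation (`> 0`).
#' @export
consistency_loss <- function(c_pi, c_pu, sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (length(c_pi) != length(c_pu))
    stop("size mismatch", call. = FALSE)
  mean((as.numeric(c_pi) - as.numeric(c_pu))^2) / sigma^2
}

#' Variance-scaled data loss for the fractional Maxwell problem
#'
#' Sum of the stress and strain regression losses, each scaled by the variance
#' of its own reference series.
#'
#' @param tau_pred,eps_pred Predicted stress and strain.
#' @param data A [stress_strain_series()].
#' @export
data_loss_fm <- function(tau_pred, eps_pred, data) {
  stopifnot(inherits(data, "stress_strain_series"))
  st <- data$stress$sigma; se <- data$strain$sigma
  if (st <= 0 || se <= 0)
    stop("stress and strain series must have positive standard deviation",
         call. = FALSE)
  mean((as.numeric(tau_pred) - data$stress$values)^2) / st^2 +
    mean((as.numeric(eps_pred) - data$strain$values)^2) / se^2
}

#' Relative error of a prediction
#'
#' For scalars, \eqn{|pred - ref| / |ref|}; for curves on matched evaluation
#' points, the L2 ratio \eqn{\|pred - ref\|_2 / \|ref\|_2}. Both are the
#' special cases of one formula and both are dimensionless.
#'
#' @param pred Predicted scalar or curve.
#' @param ref Reference scalar or curve (non-zero norm).
#' @return The relative error as a fraction.
#' @examples
#' relative_error(0.311, 0.3)
#' @export
relative_error <- function(pred, ref) {
  pred <- as.numeric(pred); ref <- as.numeric(ref)
  if (length(pred) != length(ref))
    stop("`pred` and `ref` must have matched evaluation points", call. = FALSE)
  nref <- sqrt(sum(ref^2))
  if (nref == 0) stop("reference has zero norm", call. = FALSE)
  sqrt(sum((pred - ref)^2)) / nref
}
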