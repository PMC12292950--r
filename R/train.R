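#' Training configuration
#'
#' Optimization settings shared by both inverse solvers: full-batch Adam under
#' a cosine learning-rate schedule decaying from `lr_max` to `lr_min`. The
#' default desk-scale budget of 20000 iterations completes the benchmark
#' problems in minutes on one CPU; larger budgets (the reference studies used
#' 100000) are available by configuration.
#'
#' @param iterations Total iterations `T_max`.
#' @param lr_max Maximum (initial) learning rate.
#' @param lr_min Minimum (final) learning rate.
#' @param schedule Only `"cosine"` is supported.
#' @param seed Integer seed controlling network initialization (and nothing
#'   else: training is full-batch and deterministic given the seed).
#' @param log_every Record the loss trace every this many iterations.
#' @param phys_lr_mult Learning-rate multiplier for the physical scalars
#'   (fractional orders, `kappa`, `eta`) relative to the network weights.
#'   The scalars travel through saturating transforms (logistic, softplus)
#'   and a handful of them must cross a long stretch of parameter space while
#'   thousands of network weights each move a little; a moderately larger
#'   rate equalizes the two time scales (default 5).
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(iterations = 20000L, lr_max = 2.5e-3,
                         lr_min = 2.5e-6, schedule = "cosine", seed = 1L,
                         log_every = 100L, phys_lr_mult = 5) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  if (lr_min > lr_max) stop("`lr_min` must be <= `lr_max`", call. = FALSE)
  if (phys_lr_mult <= 0) stop("`phys_lr_mult` must be positive", call. = FALSE)
  schedule <- match.arg(schedule, "cosine")
  structure(list(iterations = iterations, lr_max = lr_max, lr_min = lr_min,
                 schedule = schedule, seed = as.integer(seed),
                 log_every = as.integer(log_every),
                 phys_lr_mult = phys_lr_mult),
            class = "train_config")
}

#' Cosine learning-rate schedule
#'
#' \deqn{A = A_{min} + \tfrac12 (A_{max} - A_{min})
#'       \left(1 + \cos\frac{T_{cur}}{T_{max}}\pi\right)}
#' so the rate starts at `lr_max` (`t_cur = 0`) and ends at `lr_min`
#' (`t_cur = T_max`).
#'
#' @param t_cur Current iteration, `0 <= t_cur <= iterations`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
cosine_lr <- function(t_cur, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (any(t_cur < 0) || any(t_cur > cfg$iterations))
    stop("`t_cur` must lie in [0, iterations]", call. = FALSE)
  cfg$lr_min + 0.5 * (cfg$lr_max - cfg$lr_min) *
    (1 + cos(pi * t_cur / cfg$iterations))
}

# ---- Adam optimizer over a flat list of parameter arrays -----------------

adam_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, params, grads, lr, lr_scale = NULL) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    li <- if (is.null(lr_scale)) lr else lr * lr_scale[i]
    params[[i]] <- params[[i]] -
      li * (state$m[[i]] / c1) / (sqrt(state$v[[i]] / c2) + state$eps)
  }
  list(state = state, params = params)
}
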