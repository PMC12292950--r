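#' Calibrate fractional Maxwell parameters from stress-strain series
#'
#' The inverse solver for fractional viscoelasticity: two surrogates
#' `t -> tau^pu` and `t -> eps^pu` (default 2 hidden layers x 20 neurons,
#' swish) are regressed onto the data while the four physical parameters are
#' learned through the consistency loss built from the rearranged constitutive
#' law
#' \deqn{\tau^{pi}(t_{k+1}) = \kappa L^\nu_t \epsilon^{pu}(t_{k+1})
#'       - \eta L^\mu_t \tau^{pu}(t_{k+1}),}
#' with both fractional derivatives taken by the L1 operator on the data's
#' uniform grid. `kappa` and `eta` are softplus-transformed, `mu` and `nu`
#' logistic-transformed (so decoded values always satisfy `kappa, eta > 0` and
#' `mu, nu` in `(0, 1)`); all four start at the transform of raw zero. The
#' total loss is the unit-weight sum of the stress and strain data losses and
#' the stress consistency loss, each scaled by the variance of its reference
#' series.
#'
#' @param data A [stress_strain_series()]; both series need positive standard
#'   deviation.
#' @param netspec Architecture of the stress and strain surrogates.
#' @param cfg A [train_config()].
#' @param truth Optional [fm_params()] ground truth for error reporting.
#' @param ramp_steps Number of initial grid intervals treated as loading ramp
#'   when evaluating the relaxation-modulus error (default 5).
#' @param verbose Print progress every `cfg$log_every` iterations.
#' @return A `"fracpinn_fit"` object with decoded parameters in `$fm`
#'   (an [fm_params()] when they satisfy the order constraint, otherwise a
#'   plain list), the predicted relaxation modulus function `gt_fn`, the loss
#'   trace, and relative errors when `truth` is given.
#' @export
fit_fractional_maxwell <- function(data,
                                   netspec = network_spec(2, 20, input_dim = 1),
                                   cfg = train_config(),
                                   truth = NULL,
                                   ramp_steps = 5L,
                                   verbose = FALSE) {
  stopifnot(inherits(data, "stress_strain_series"), inherits(cfg, "train_config"))
  st <- data$stress$sigma; se <- data$strain$sigma
  if (st <= 0) stop("stress series is constant (sigma = 0)", call. = FALSE)
  if (se <= 0) stop("strain series is constant (sigma = 0)", call. = FALSE)
  n <- data$grid$n_steps
  dt <- data$grid$dt
  tt <- grid_times(data$grid)
  # sqrt-warped time input (then affine to [-1, 1]): fractional relaxation is
  # steep at early times and the warp lets the small surrogates resolve the
  # loading ramp; the L1 operators act on values, not on this parameterization
  ts <- sqrt(tt - min(tt))
  tn <- matrix(2 * ts / max(ts) - 1, ncol = 1)
  Yt <- matrix(data$stress$values, ncol = 1)
  Ye <- matrix(data$strain$values, ncol = 1)

  ptau <- mlp_init(netspec, seed = cfg$seed)
  peps <- mlp_init(netspec, seed = cfg$seed + 1L)
  npn <- length(ptau)
  params <- c(ptau, peps,
              list(matrix(0, 1, 1), matrix(0, 1, 1),     # kappa_raw, eta_raw
                   matrix(0, 1, 1), matrix(0, 1, 1)))    # mu_raw, nu_raw
  opt <- adam_new(params)
  lr_scale <- c(rep(1, 2L * npn), rep(cfg$phys_lr_mult, 4L))

  trace <- trace_new(cfg)
  final <- NULL
  for (it in seq_len(cfg$iterations)) {
    tp <- tp_new()
    pids <- lapply(params, function(p) tp_var(tp, p))
    xid <- tp_var(tp, tn)

    tau_pu <- mlp_forward(tp, pids[seq_len(npn)], xid)
    eps_pu <- mlp_forward(tp, pids[npn + seq_len(npn)], xid)
    dloss <- tp_add(tp,
      tp_cmul(tp, tp_mean(tp, tp_square(tp, tp_sub(tp, tau_pu, tp_var(tp, Yt)))),
              1 / st^2),
      tp_cmul(tp, tp_mean(tp, tp_square(tp, tp_sub(tp, eps_pu, tp_var(tp, Ye)))),
              1 / se^2))

    kap <- tp_softplus(tp, pids[[2L * npn + 1L]])
    eta <- tp_softplus(tp, pids[[2L * npn + 2L]])
    mu <- tp_sigmoid(tp, pids[[2L * npn + 3L]])
    nu <- tp_sigmoid(tp, pids[[2L * npn + 4L]])

    Lnu_eps <- tp_caputo(tp, eps_pu, nu, dt)
    Lmu_tau <- tp_caputo(tp, tau_pu, mu, dt)
    tau_pi <- tp_sub(tp, tp_smul(tp, Lnu_eps, kap), tp_smul(tp, Lmu_tau, eta))
    tau_tail <- tp_subset(tp, tau_pu, 2:(n + 1L), NULL)
    closs <- tp_cmul(tp, tp_mean(tp, tp_square(tp, tp_sub(tp, tau_pi, tau_tail))),
                     1 / st^2)
    total <- tp_add(tp, dloss, closs)

    lval <- tp_value(tp, total)
    if (!is.finite(lval))
      stop_divergence("fit_fractional_maxwell", it, trace_df(trace))

    grads <- tp_backward(tp, total)
    glist <- lapply(seq_along(params), function(i) {
      g <- grads[[pids[[i]]]]
      if (is.null(g)) params[[i]] * 0 else g
    })
    lr <- cosine_lr(it, cfg)
    stp <- adam_step(opt, params, glist, lr, lr_scale)
    opt <- stp$state; params <- stp$params

    if (it %% cfg$log_every == 0L || it == cfg$iterations) {
      dec <- decode_fm_raw(params, npn)
      trace <- trace_push(trace, it, lr, tp_value(tp, dloss),
                          tp_value(tp, closs), lval,
                          alpha = dec$mu,
                          min_pos = min(dec$kappa, dec$eta))
      if (verbose)
        message(sprintf("it %6d data %.4e cons %.4e k %.3f e %.3f mu %.3f nu %.3f",
                        it, tp_value(tp, dloss), tp_value(tp, closs),
                        dec$kappa, dec$eta, dec$mu, dec$nu))
    }
    if (it == cfg$iterations)
      final <- list(data = tp_value(tp, dloss),
                    consistency = tp_value(tp, closs), total = lval)
  }

  dec <- decode_fm_raw(params, npn)
  fm <- tryCatch(fm_params(dec$kappa, dec$eta, dec$mu, dec$nu),
                 error = function(e) dec)
  gt_fn <- function(t) {
    (dec$kappa / dec$eta) * t^(dec$mu - dec$nu) *
      mittag_leffler(dec$mu, 1 + dec$mu - dec$nu, -t^dec$mu / dec$eta)
  }
  rel <- NULL
  if (!is.null(truth)) {
    t_eval <- tt[tt > ramp_steps * dt + 1e-12]
    rel <- list(kappa = relative_error(dec$kappa, truth$kappa),
                eta = relative_error(dec$eta, truth$eta),
                mu = relative_error(dec$mu, truth$mu),
                nu = relative_error(dec$nu, truth$nu),
                gt = relative_error(gt_fn(t_eval),
                                    relaxation_modulus(truth, t_eval)))
  }
  structure(list(problem = "fractional_maxwell",
                 fm = fm, gt_fn = gt_fn,
                 losses = final, trace = trace_df(trace), rel_err = rel,
                 params = list(tau_net = params[seq_len(npn)],
                               eps_net = params[npn + seq_len(npn)]),
                 netspec = netspec, cfg = cfg,
                 sigma_tau = st, sigma_eps = se),
            class = "fracpinn_fit")
}

decode_fm_raw <- function(params, npn) {
  list(kappa = softplus(params[[2L * npn + 1L]][1, 1]),
       eta = softplus(params[[2L * npn + 2L]][1, 1]),
       mu = logistic(params[[2L * npn + 3L]][1, 1]),
       nu = logistic(params[[2L * npn + 4L]][1, 1]))
}
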