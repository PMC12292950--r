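#' Physics-informed reconstruction of a concentration field
#'
#' Rebuilds the field through the discretized governing equation:
#' \deqn{c^{pi}(t_{k+1}, x) = \Gamma(2-\alpha)\,\Delta t^\alpha\,
#'   g(c(t_{k+1}, x), \tilde D) + h(c(\cdot, x), t_k),}
#' with spatial derivatives by second-order central differences on the field's
#' grid and the L1 history term in time. The diffusion term `g` is evaluated
#' at the target level \eqn{t_{k+1}} (implicit flavor, matching the forward
#' solver's stencil); evaluating it one level earlier leaves an O(1) residual
#' bias on fields with fast early transients. When `field` solves the
#' time-fractional diffusion equation for (`law`, `alpha`), the reconstruction
#' reproduces the field at \eqn{t_{k+1}} up to the scheme's discretization
#' error; the mismatch is what the consistency loss of
#' [fit_anomalous_diffusion()] penalizes (there, with the surrogate network in
#' place of the data and the learned coefficient network in place of `law`).
#'
#' @param field An [st_field()] (data, exact solution, or surrogate samples).
#' @param law A [diffusion_law()].
#' @param alpha Fractional order in `[0, 1]`.
#' @return A list with `cpi` and `cpu` arrays of dimension
#'   `(n_steps, nx - 2, ny - 2)` (interior points, times `t_1..t_n`), plus the
#'   interior coordinates.
#' @export
physics_informed_concentration <- function(field, law, alpha) {
  stopifnot(inherits(field, "st_field"), inherits(law, "diffusion_law"))
  check_order(alpha)
  nx <- length(field$x); ny <- length(field$y)
  nt <- field$grid$n_steps
  hx <- field$x[2] - field$x[1]; hy <- field$y[2] - field$y[1]
  dt <- field$grid$dt
  pref <- gamma(2 - alpha) * dt^alpha
  H <- history_matrix(alpha, nt)
  ixi <- 2:(nx - 1L); iyi <- 2:(ny - 1L)
  v <- field$values

  cpi <- array(NA_real_, c(nt, nx - 2L, ny - 2L))
  # history: apply H along the time axis at each interior spatial point
  cint <- matrix(aperm(v[, ixi, iyi, drop = FALSE], c(2, 3, 1)),
                 ncol = nt + 1L)                      # (nint x nt+1)
  hist_all <- tcrossprod(cint, H)                     # (nint x nt)
  for (k in 0:(nt - 1L)) {
    ck <- v[k + 2L, , ]                               # g at the target level
    cxx <- (ck[3:nx, iyi] - 2 * ck[ixi, iyi] + ck[1:(nx - 2L), iyi]) / hx^2
    cyy <- (ck[ixi, 3:ny] - 2 * ck[ixi, iyi] + ck[ixi, 1:(ny - 2L)]) / hy^2
    cx <- (ck[3:nx, iyi] - ck[1:(nx - 2L), iyi]) / (2 * hx)
    cy <- (ck[ixi, 3:ny] - ck[ixi, 1:(ny - 2L)]) / (2 * hy)
    ci <- ck[ixi, iyi]
    g <- law$dcoef(ci) * (cxx + cyy) + law$dcoef_deriv(ci) * (cx^2 + cy^2)
    cpi[k + 1L, , ] <- pref * g + matrix(hist_all[, k + 1L], nx - 2L, ny - 2L)
  }
  cpu <- v[2:(nt + 1L), ixi, iyi, drop = FALSE]
  list(cpi = cpi, cpu = cpu, x = field$x[ixi], y = field$y[iyi])
}

#' Jointly recover the fractional order and the diffusion-coefficient law
#'
#' The inverse solver for anomalous diffusion: a concentration surrogate
#' `c^pu(t, x, y; theta)` (default 4 hidden layers x 16 neurons, swish), a
#' coefficient surrogate `D(c; phi)` (default 2 x 4, softplus output head so
#' the coefficient stays positive), and a scalar fractional order `alpha`
#' (logistic transform of an unconstrained raw value, initialized at 0.5) are
#' trained jointly by full-batch Adam under the cosine schedule, minimizing
#' the unit-weight sum of the variance-scaled data loss and the consistency
#' loss built from [physics_informed_concentration()]'s discrete operator
#' (history term plus L1 prefactor, central spatial differences of the
#' surrogate on the observation grid, coefficient derivative from the
#' coefficient network).
#'
#' Network inputs are affinely mapped to `[-1, 1]`; outputs stay in physical
#' units (the losses are already variance-scaled). The consistency loss runs
#' over the interior points of the observation grid at all time levels — the
#' L1 stencil needs the surrogate's full time history at fixed spatial
#' locations.
#'
#' @param data An [st_field()] of (possibly noisy) observations; must have
#'   `sigma_c > 0`.
#' @param netspec_c Architecture of the concentration surrogate.
#' @param netspec_d Architecture of the coefficient surrogate.
#' @param cfg A [train_config()].
#' @param truth Optional list with elements `alpha` and `law` (the generating
#'   truth); enables relative-error reporting.
#' @param verbose Print progress every `cfg$log_every` iterations.
#' @return An object of class `"fracpinn_fit"` with the decoded order
#'   `alpha`, the learned coefficient function `dcoef_fn`, the loss `trace`
#'   (a data frame), final losses, relative errors (when `truth` given), and
#'   everything needed to reproduce the run.
#' @export
fit_anomalous_diffusion <- function(data,
                                    netspec_c = network_spec(4, 16, input_dim = 3),
                                    netspec_d = network_spec(2, 4, input_dim = 1),
                                    cfg = train_config(),
                                    truth = NULL,
                                    verbose = FALSE) {
  stopifnot(inherits(data, "st_field"), inherits(cfg, "train_config"))
  if (data$sigma_c <= 0)
    stop("data field is constant (sigma_c = 0); the variance-scaled losses are undefined",
         call. = FALSE)
  nx <- length(data$x); ny <- length(data$y)
  nt <- data$grid$n_steps
  nspace <- nx * ny
  dt <- data$grid$dt
  sig2 <- data$sigma_c^2

  # normalized inputs on the (space fastest, then time) tensor grid; the time
  # axis is square-root warped before the affine map: sub-diffusive fields
  # evolve on a t^alpha clock, and the warp lets the small surrogate resolve
  # the fast early transient instead of spending its capacity on a near-jump
  norm01 <- function(v) if (diff(range(v)) == 0) v * 0 else
    2 * (v - min(v)) / diff(range(v)) - 1
  tt_raw <- grid_times(data$grid)
  tn <- norm01(sqrt(tt_raw - min(tt_raw)))
  xn <- norm01(data$x); yn <- norm01(data$y)
  Xn <- cbind(rep(tn, each = nspace),
              rep(rep(xn, times = ny), times = nt + 1L),
              rep(rep(yn, each = nx), times = nt + 1L))
  Y <- matrix(as.numeric(aperm(data$values, c(2, 3, 1))), ncol = 1)

  hx <- data$x[2] - data$x[1]; hy <- data$y[2] - data$y[1]
  ops <- spatial_ops(nx, ny, hx, hy)
  iidx <- ops$interior
  nint <- length(iidx)

  crng <- stats::quantile(data$values, c(0, 1), names = FALSE)
  cmid <- mean(crng); chalf <- diff(crng) / 2
  if (chalf <= 0) chalf <- 1
  hh <- 1e-3   # FD step (normalized input units) for the D_c derivative

  pc <- mlp_init(netspec_c, seed = cfg$seed)
  pd <- mlp_init(netspec_d, seed = cfg$seed + 1L)
  params <- c(pc, pd, list(matrix(0, 1, 1)))   # last entry: alpha_raw
  npc <- length(pc); npd <- length(pd)
  opt <- adam_new(params)
  lr_scale <- c(rep(1, npc + npd), cfg$phys_lr_mult)

  trace <- trace_new(cfg)
  final <- NULL
  for (it in seq_len(cfg$iterations)) {
    tp <- tp_new()
    pids <- lapply(params, function(p) tp_var(tp, p))
    xid <- tp_var(tp, Xn)
    yid <- tp_var(tp, Y)

    cvec <- mlp_forward(tp, pids[seq_len(npc)], xid)
    dloss <- tp_cmul(tp, tp_mean(tp, tp_square(tp, tp_sub(tp, cvec, yid))),
                     1 / sig2)

    cmat <- tp_reshape(tp, cvec, c(nspace, nt + 1L))
    alpha_n <- tp_sigmoid(tp, pids[[npc + npd + 1L]])

    cx <- tp_spmm(tp, ops$sx, cmat)
    cy <- tp_spmm(tp, ops$sy, cmat)
    cxx <- tp_spmm(tp, ops$sxx, cmat)
    cyy <- tp_spmm(tp, ops$syy, cmat)
    kcols <- 2:(nt + 1L)          # diffusion term at the target time level
    ck <- tp_subset(tp, cmat, iidx, kcols)
    lap <- tp_add(tp, tp_subset(tp, cxx, iidx, kcols),
                  tp_subset(tp, cyy, iidx, kcols))
    grad2 <- tp_add(tp, tp_square(tp, tp_subset(tp, cx, iidx, kcols)),
                    tp_square(tp, tp_subset(tp, cy, iidx, kcols)))

    cn <- tp_cmul(tp, tp_cadd(tp, tp_reshape(tp, ck, c(nint * nt, 1L)), -cmid),
                  1 / chalf)
    dids <- pids[npc + seq_len(npd)]
    Dmid <- tp_softplus(tp, mlp_forward(tp, dids, cn))
    Dup <- tp_softplus(tp, mlp_forward(tp, dids, tp_cadd(tp, cn, hh)))
    Ddn <- tp_softplus(tp, mlp_forward(tp, dids, tp_cadd(tp, cn, -hh)))
    Dc <- tp_cmul(tp, tp_sub(tp, Dup, Ddn), 1 / (2 * hh * chalf))
    Dm <- tp_reshape(tp, Dmid, c(nint, nt))
    Dcm <- tp_reshape(tp, Dc, c(nint, nt))

    gterm <- tp_add(tp, tp_mul(tp, Dm, lap), tp_mul(tp, Dcm, grad2))
    pref <- tp_prefactor(tp, alpha_n, dt)
    cint_full <- tp_subset(tp, cmat, iidx, NULL)
    hterm <- tp_history(tp, cint_full, alpha_n, nt)
    cpi <- tp_add(tp, tp_smul(tp, gterm, pref), hterm)
    cpu_tail <- tp_subset(tp, cmat, iidx, 2:(nt + 1L))
    closs <- tp_cmul(tp, tp_mean(tp, tp_square(tp, tp_sub(tp, cpi, cpu_tail))),
                     1 / sig2)
    total <- tp_add(tp, dloss, closs)

    lval <- tp_value(tp, total)
    if (!is.finite(lval))
      stop_divergence("fit_anomalous_diffusion", it, trace_df(trace))

    grads <- tp_backward(tp, total)
    glist <- lapply(seq_along(params), function(i) {
      g <- grads[[tp_id_of(pids, i)]]
      if (is.null(g)) params[[i]] * 0 else g
    })
    lr <- cosine_lr(it, cfg)
    st <- adam_step(opt, params, glist, lr, lr_scale)
    opt <- st$state; params <- st$params

    if (it %% cfg$log_every == 0L || it == cfg$iterations) {
      av <- logistic(params[[npc + npd + 1L]][1, 1])
      dmin <- min(tp_value(tp, Dmid))
      trace <- trace_push(trace, it, lr, tp_value(tp, dloss),
                          tp_value(tp, closs), lval,
                          alpha = av, min_pos = dmin)
      if (verbose)
        message(sprintf("it %6d lr %.2e data %.4e cons %.4e alpha %.4f",
                        it, lr, tp_value(tp, dloss), tp_value(tp, closs), av))
    }
    if (it == cfg$iterations)
      final <- list(data = tp_value(tp, dloss), consistency = tp_value(tp, closs),
                    total = lval)
  }

  pc <- params[seq_len(npc)]
  pd <- params[npc + seq_len(npd)]
  alpha_hat <- logistic(params[[npc + npd + 1L]][1, 1])
  dcoef_fn <- function(c) {
    as.numeric(softplus(mlp_eval(pd, matrix((c - cmid) / chalf, ncol = 1))))
  }
  cq <- stats::quantile(data$values, c(0.01, 0.99), names = FALSE)
  rel <- NULL
  if (!is.null(truth)) {
    cgrid <- seq(cq[1], cq[2], length.out = 201L)
    rel <- list(alpha = relative_error(alpha_hat, truth$alpha),
                dcoef = relative_error(dcoef_fn(cgrid),
                                       truth$law$dcoef(cgrid)))
  }
  structure(list(problem = "anomalous_diffusion",
                 alpha = alpha_hat, dcoef_fn = dcoef_fn,
                 c_range = cq,
                 losses = final, trace = trace_df(trace),
                 rel_err = rel,
                 params = list(c_net = pc, d_net = pd,
                               input_norm = list(cmid = cmid, chalf = chalf)),
                 netspec_c = netspec_c, netspec_d = netspec_d,
                 cfg = cfg, sigma_c = data$sigma_c),
            class = "fracpinn_fit")
}

# position of the i-th parameter's node id (parameters are the first nodes)
tp_id_of <- function(pids, i) pids[[i]]

#' @export
print.fracpinn_fit <- function(x, ...) {
  cat(sprintf("<fracpinn_fit> %s\n", x$problem))
  if (x$problem == "anomalous_diffusion") {
    cat(sprintf("  alpha = %.4f\n", x$alpha))
  } else {
    cat(sprintf("  kappa = %.4g, eta = %.4g, mu = %.4f, nu = %.4f\n",
                x$fm$kappa, x$fm$eta, x$fm$mu, x$fm$nu))
  }
  cat(sprintf("  losses: data %.4e + consistency %.4e = %.4e\n",
              x$losses$data, x$losses$consistency, x$losses$total))
  if (!is.null(x$rel_err)) {
    cat("  relative errors:",
        paste(sprintf("%s %.3g", names(x$rel_err), unlist(x$rel_err)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# sparse central-difference operators on the flattened (x fastest) grid
spatial_ops <- function(nx, ny, hx, hy) {
  id <- matrix(seq_len(nx * ny), nx, ny)
  ixi <- 2:(nx - 1L); iyi <- 2:(ny - 1L)
  interior <- as.vector(id[ixi, iyi])
  ctr <- as.vector(id[ixi, iyi])
  xp <- as.vector(id[3:nx, iyi]); xm <- as.vector(id[1:(nx - 2L), iyi])
  yp <- as.vector(id[ixi, 3:ny]); ym <- as.vector(id[ixi, 1:(ny - 2L)])
  n <- nx * ny
  sp <- function(i, j, v) Matrix::sparseMatrix(i = i, j = j, x = v,
                                               dims = c(n, n))
  list(
    sx  = sp(c(ctr, ctr), c(xp, xm), c(rep(1 / (2 * hx), length(ctr)),
                                       rep(-1 / (2 * hx), length(ctr)))),
    sy  = sp(c(ctr, ctr), c(yp, ym), c(rep(1 / (2 * hy), length(ctr)),
                                       rep(-1 / (2 * hy), length(ctr)))),
    sxx = sp(c(ctr, ctr, ctr), c(xp, ctr, xm),
             c(rep(1 / hx^2, length(ctr)), rep(-2 / hx^2, length(ctr)),
               rep(1 / hx^2, length(ctr)))),
    syy = sp(c(ctr, ctr, ctr), c(yp, ctr, ym),
             c(rep(1 / hy^2, length(ctr)), rep(-2 / hy^2, length(ctr)),
               rep(1 / hy^2, length(ctr)))),
    interior = interior
  )
}

# loss-trace helpers (preallocated, grown geometrically)
trace_new <- function(cfg) {
  n <- ceiling(cfg$iterations / cfg$log_every) + 2L
  list(i = 0L, it = integer(n), lr = numeric(n), data = numeric(n),
       cons = numeric(n), total = numeric(n), alpha = numeric(n),
       min_pos = numeric(n))
}

trace_push <- function(tr, it, lr, data, cons, total, alpha = NA_real_,
                       min_pos = NA_real_) {
  tr$i <- tr$i + 1L
  i <- tr$i
  tr$it[i] <- it; tr$lr[i] <- lr; tr$data[i] <- data; tr$cons[i] <- cons
  tr$total[i] <- total; tr$alpha[i] <- alpha; tr$min_pos[i] <- min_pos
  tr
}

trace_df <- function(tr) {
  i <- seq_len(tr$i)
  data.frame(iteration = tr$it[i], lr = tr$lr[i], data_loss = tr$data[i],
             consistency_loss = tr$cons[i], total_loss = tr$total[i],
             alpha = tr$alpha[i], min_positive = tr$min_pos[i])
}

stop_divergence <- function(where, it, trace) {
  cond <- structure(
    class = c("fracpinn_divergence", "error", "condition"),
    list(message = sprintf("%s: non-finite loss at iteration %d", where, it),
         call = NULL, trace = trace))
  stop(cond)
}
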