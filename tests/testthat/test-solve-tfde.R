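test_that("zero initial and boundary data give the zero field", {
  sc <- diffusion_scenario(alpha = 0.4, nx = 10, ny = 10, n_steps = 6,
                           ic = function(x, y) 0 * x)
  fld <- solve_tfde(sc)
  expect_true(all(fld$values == 0))
  expect_equal(fld$sigma_c, 0)
})

test_that("alpha = 1 with constant coefficient matches the separable heat
           solution under refinement", {
  heat_err <- function(nx, nsteps) {
    sc <- diffusion_scenario(alpha = 1, law = constant_diffusion_law(0.1),
                             nx = nx, ny = nx, n_steps = nsteps,
                             ic = function(x, y) sin(pi * x) * sin(pi * y))
    fld <- solve_tfde(sc)
    tt <- grid_times(fld$grid)
    X <- outer(fld$x, rep(1, nx)); Y <- outer(rep(1, nx), fld$y)
    mx <- 0
    for (k in seq_along(tt)) {
      ex <- exp(-2 * pi^2 * 0.1 * tt[k]) * sin(pi * X) * sin(pi * Y)
      mx <- max(mx, max(abs(fld$values[k, , ] - ex)))
    }
    mx
  }
  coarse <- heat_err(24, 20)
  fine <- heat_err(48, 80)
  expect_lt(fine, coarse / 2)     # error shrinks under joint refinement
  expect_lt(coarse, 0.05)
})

test_that("manufactured solution shows temporal order about 2 - alpha", {
  # c* = t^2 x(1-x) y(1-y): spatially cubic, so the central differences are
  # exact and the remaining error is the L1 scheme's O(dt^(2-alpha))
  a <- 0.5; D <- 0.1
  errs <- vapply(c(10, 20, 40, 80), function(ns) {
    sc <- diffusion_scenario(
      alpha = a, law = constant_diffusion_law(D), nx = 12, ny = 12,
      n_steps = ns, ic = function(x, y) 0 * x,
      source = function(t, x, y)
        gamma(3) * t^(2 - a) / gamma(3 - a) * x * (1 - x) * y * (1 - y) +
        2 * D * t^2 * (x * (1 - x) + y * (1 - y)))
    fld <- solve_tfde(sc)
    tt <- grid_times(fld$grid)
    X <- outer(fld$x, rep(1, 12)); Y <- outer(rep(1, 12), fld$y)
    mx <- 0
    for (k in seq_along(tt))
      mx <- max(mx, max(abs(fld$values[k, , ] -
                              tt[k]^2 * X * (1 - X) * Y * (1 - Y))))
    mx
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(errs) ~ log(1 / c(10, 20, 40, 80))))[2]
  expect_gt(slope, 2 - a - 0.15)
  expect_lt(slope, 2 - a + 0.15)
})

test_that("sub-diffusion slows the late-time decay of the peak", {
  peaks <- vapply(c(0.3, 0.5, 0.7, 1.0), function(a) {
    sc <- diffusion_scenario(alpha = a, law = constant_diffusion_law(0.1),
                             nx = 24, ny = 24, n_steps = 20)
    fld <- solve_tfde(sc)
    max(fld$values[21, , ])
  }, numeric(1))
  # smaller order -> heavier memory -> higher remaining peak at t = 1
  expect_true(all(diff(peaks) < 0))
})

test_that("solver results are reproducible and nonlinearity matters", {
  sc <- diffusion_scenario(alpha = 0.5, nx = 12, ny = 12, n_steps = 8)
  f1 <- solve_tfde(sc); f2 <- solve_tfde(sc)
  expect_identical(f1$values, f2$values)
  # concentration-dependent law differs from its constant-law counterpart
  scc <- diffusion_scenario(alpha = 0.5, law = constant_diffusion_law(0.1),
                            nx = 12, ny = 12, n_steps = 8)
  fc <- solve_tfde(scc)
  expect_gt(max(abs(f1$values - fc$values)), 1e-4)
})

test_that("physics_informed_concentration reduces correctly in its limit
           cases and is consistent with the forward solver", {
  sc <- diffusion_scenario(alpha = 0.55, nx = 14, ny = 14, n_steps = 12)
  fld <- solve_tfde(sc)
  # D == 0: reconstruction is the bare history term
  zero_law <- diffusion_law(function(c) 0 * c, function(c) 0 * c)
  pic0 <- physics_informed_concentration(fld, zero_law, 0.55)
  H <- history_matrix(0.55, 12)
  ci <- matrix(aperm(fld$values[, 2:13, 2:13], c(2, 3, 1)), ncol = 13)
  href <- tcrossprod(ci, H)
  expect_equal(as.numeric(aperm(pic0$cpi, c(2, 3, 1))), as.numeric(href),
               tolerance = 1e-12)
  # alpha = 1: one-step implicit-Euler form c(t_k) + dt * g(c(t_{k+1}))
  law <- sc$law
  pic1 <- physics_informed_concentration(fld, law, 1)
  k <- 4L                          # reconstruction target t_4
  ck <- fld$values[k + 1L, , ]     # diffusion term at the target level
  nx <- 14; hx <- fld$x[2] - fld$x[1]
  ixi <- 2:13
  cxx <- (ck[3:14, ixi] - 2 * ck[ixi, ixi] + ck[1:12, ixi]) / hx^2
  cyy <- (ck[ixi, 3:14] - 2 * ck[ixi, ixi] + ck[ixi, 1:12]) / hx^2
  cx <- (ck[3:14, ixi] - ck[1:12, ixi]) / (2 * hx)
  cy <- (ck[ixi, 3:14] - ck[ixi, 1:12]) / (2 * hx)
  gk <- law$dcoef(ck[ixi, ixi]) * (cxx + cyy) +
    law$dcoef_deriv(ck[ixi, ixi]) * (cx^2 + cy^2)
  expect_equal(pic1$cpi[k, , ], fld$values[k, ixi, ixi] + fld$grid$dt * gk,
               tolerance = 1e-12)
  # fed the exact discrete solution and the true law, the reconstruction
  # re-applies the forward solver's own stencil, so the residual collapses to
  # the solver's Picard tolerance at every resolution — while a wrong order
  # leaves an O(1) residual
  errs <- vapply(c(10, 20, 40), function(ns) {
    sci <- diffusion_scenario(alpha = 0.55, nx = 14, ny = 14, n_steps = ns)
    fi <- solve_tfde(sci)
    pic <- physics_informed_concentration(fi, sci$law, 0.55)
    relative_error(as.numeric(pic$cpi), as.numeric(pic$cpu))
  }, numeric(1))
  expect_lt(max(errs), 1e-7)
  sci <- diffusion_scenario(alpha = 0.55, nx = 14, ny = 14, n_steps = 20)
  fi <- solve_tfde(sci)
  pic_wrong <- physics_informed_concentration(fi, sci$law, 0.8)
  expect_gt(relative_error(as.numeric(pic_wrong$cpi), as.numeric(pic_wrong$cpu)),
            1e-2)
})
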