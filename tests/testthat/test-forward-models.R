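test_that("diffusion_rhs evaluates the chain-rule expansion", {
  cl <- constant_diffusion_law(0.5)
  d0 <- field_derivatives(c = 1, cx = 0, cy = 0, cxx = 0, cyy = 0)
  expect_equal(diffusion_rhs(d0, cl), 0)
  d1 <- field_derivatives(c = 1, cx = 4, cy = -2, cxx = 2, cyy = 3)
  expect_equal(diffusion_rhs(d1, cl), 0.5 * 5)   # constant law: D * laplacian
  # law D(c) = c: g = c (cxx + cyy) + (cx^2 + cy^2); at c=1, cx=1, rest 0 -> 1,
  # the symbolic expansion of div(D(c) grad c) for this law
  lin <- diffusion_law(function(c) c, function(c) rep(1, length(c)))
  d2 <- field_derivatives(c = 1, cx = 1, cy = 0, cxx = 0, cyy = 0)
  expect_equal(diffusion_rhs(d2, lin), 1)
  # vectorized evaluation and agreement with a finite-difference check of the
  # declared analytic derivative of the default law
  law <- default_diffusion_law()
  cc <- seq(0, 1, by = 0.1)
  fd <- (law$dcoef(cc + 1e-6) - law$dcoef(cc - 1e-6)) / 2e-6
  expect_equal(law$dcoef_deriv(cc), fd, tolerance = 1e-8)
})

test_that("relaxation modulus: classical Maxwell limit, mu = nu limit, and
           oracle values", {
  # mu = nu = 1: G(t) = (kappa/eta) exp(-t/eta)
  p <- fm_params(2, 0.5, 1, 1)
  expect_equal(relaxation_modulus(p, 1), 4 * exp(-2), tolerance = 1e-12)
  tt <- seq(0.1, 3, by = 0.1)
  expect_equal(relaxation_modulus(p, tt), 4 * exp(-tt / 0.5),
               tolerance = 1e-10)
  # mu = nu: G(0+) = kappa / eta exactly
  p2 <- fm_params(1.5, 0.6, 0.5, 0.5)
  expect_equal(relaxation_modulus(p2, 0), 1.5 / 0.6)
  expect_equal(relaxation_modulus(p2, 1e-9), 1.5 / 0.6, tolerance = 1e-4)
  for (i in seq_len(nrow(gt_reference))) {
    r <- gt_reference[i, ]
    p <- fm_params(r$kappa, r$eta, r$mu, r$nu)
    expect_equal(relaxation_modulus(p, r$t), r$val, tolerance = 1e-9)
  }
})

test_that("relaxation modulus is positive; t = 0 rejected unless mu = nu", {
  tt <- seq(0.05, 20, length.out = 60)
  for (p in list(fm_params(2, 0.8, 0.7, 0.2), fm_params(1, 1, 0.9, 0.9),
                 fm_params(0.5, 2, 0.4, 0.1), fm_params(3, 0.3, 1, 0.5))) {
    g <- relaxation_modulus(p, tt)
    expect_true(all(g > 0))
  }
  # monotone decay where the model implies it: equal orders
  g <- relaxation_modulus(fm_params(2, 0.8, 0.6, 0.6), tt)
  expect_true(all(diff(g) < 0))
  expect_error(relaxation_modulus(fm_params(2, 0.8, 0.7, 0.2), c(0, 1)),
               "t = 0")
})

test_that("order constraint nu <= mu is enforced with an off-switch", {
  expect_error(fm_params(1, 1, 0.3, 0.6), "constraint")
  p <- fm_params(1, 1, 0.3, 0.6, enforce_order = FALSE)
  expect_equal(p$nu, 0.6)
  expect_error(fm_params(-1, 1, 0.5, 0.5), "positive")
  expect_error(fm_params(1, 1, 1.5, 0.5), "\\[0, 1\\]")
})

test_that("stress_step_strain scales the modulus by the step strain", {
  g <- time_grid(0.05, 0.05, 40)
  p <- fm_params(2, 0.8, 0.7, 0.2)
  s0 <- stress_step_strain(p, 0, g)
  expect_true(all(s0$values == 0))
  s <- stress_step_strain(p, 1.7, g)
  expect_equal(s$values, 1.7 * relaxation_modulus(p, grid_times(g)),
               tolerance = 1e-12)
  # classical limit: log stress linear in t with slope -1/eta
  pm <- fm_params(2, 0.5, 1, 1)
  sm <- stress_step_strain(pm, 1, g)
  slopes <- diff(log(sm$values)) / g$dt
  expect_equal(slopes, rep(-1 / 0.5, g$n_steps), tolerance = 1e-9)
})

test_that("fm_physics_stress: zeros, joint linearity, grid checks", {
  g <- time_grid(0, 0.1, 15)
  p <- fm_params(1.2, 0.9, 0.8, 0.3)
  z <- scalar_series(rep(0, 16), g)
  expect_true(all(fm_physics_stress(z, z, p)$values == 0))
  e1 <- tiny_series(15, 0.1, seed = 11); t1 <- tiny_series(15, 0.1, seed = 12)
  e2 <- tiny_series(15, 0.1, seed = 13); t2 <- tiny_series(15, 0.1, seed = 14)
  a <- 1.3; b <- -0.7
  comb <- fm_physics_stress(scalar_series(a * e1$values + b * e2$values, g),
                            scalar_series(a * t1$values + b * t2$values, g), p)
  expect_equal(comb$values,
               a * fm_physics_stress(e1, t1, p)$values +
                 b * fm_physics_stress(e2, t2, p)$values,
               tolerance = 1e-11)
  g2 <- time_grid(0, 0.2, 15)
  expect_error(fm_physics_stress(scalar_series(rep(0, 16), g2), z, p),
               "shared|share")
})

test_that("physics-informed stress reproduces generated data and converges
           under grid refinement", {
  p <- fm_params(1, 1, 0.5, 0.5)
  res <- vapply(c(100, 200, 400), function(n) {
    d <- generate_fm_dataset(p, eps0 = 1, grid = time_grid(0, 10 / n, n),
                             ramp_steps = 5L)
    tpi <- fm_physics_stress(d$strain, d$stress, p)
    relative_error(tpi$values, d$stress$values[-1])
  }, numeric(1))
  # the generator integrates the same discrete law, so the residual is at
  # machine precision on every grid
  expect_true(all(res < 1e-12))
  # classical limit: tau^pi of the analytic exponential stress under constant
  # strain matches within O(dt)
  pm <- fm_params(2, 0.5, 1, 1)
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    n <- round(4 / dt)
    g <- time_grid(1, dt, n)      # start after an ideal step at t = 0
    tt <- grid_times(g)
    strain <- scalar_series(rep(1, n + 1), g)
    stress <- scalar_series(4 * exp(-tt / 0.5), g)
    tpi <- fm_physics_stress(strain, stress, pm)
    relative_error(tpi$values, stress$values[-1])
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / errs[1], 0.5)
})
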