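test_that("fractional Maxwell generator: zero strain, classical limit,
           post-ramp closed form", {
  p <- fm_params(2, 0.8, 0.7, 0.2)
  d0 <- generate_fm_dataset(p, eps0 = 0)
  expect_true(all(d0$stress$values == 0))
  # classical Maxwell: post-ramp stress approaches (kappa/eta) eps0 exp(-t/eta)
  pm <- fm_params(2, 0.5, 1, 1)
  dm <- generate_fm_dataset(pm, eps0 = 0.5, grid = time_grid(0, 0.01, 300),
                            ramp_steps = 5L)
  tt <- grid_times(dm$grid)
  post <- tt > 0.05
  expect_lt(relative_error(dm$stress$values[post],
                           (2 / 0.5) * 0.5 * exp(-tt[post] / 0.5)), 0.06)
  # post-ramp stress converges to G(t) * eps0 under refinement
  errs <- vapply(c(100, 200, 400, 800), function(n) {
    d <- generate_fm_dataset(p, eps0 = 1, grid = time_grid(0, 10 / n, n),
                             ramp_steps = 5L)
    tt <- grid_times(d$grid)
    post <- tt > 5 * d$grid$dt + 1e-12
    relative_error(d$stress$values[post],
                   relaxation_modulus(p, tt[post]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 0.01)
})

test_that("generated data satisfy the discrete constitutive law exactly and
           the strain ramp hits its endpoints", {
  p <- fm_params(2, 0.8, 0.7, 0.2)
  d <- generate_fm_dataset(p, eps0 = 1.4)
  tpi <- fm_physics_stress(d$strain, d$stress, p)
  expect_lt(relative_error(tpi$values, d$stress$values[-1]), 1e-12)
  expect_equal(d$strain$values[1], 0)
  expect_equal(d$strain$values[6], 1.4)
  expect_true(all(d$strain$values[6:201] == 1.4))
  expect_true(all(diff(d$strain$values[1:6]) > 0))
  # stress decays monotonically after its peak (the model's G rises from zero
  # for mu > nu before relaxing)
  pk <- which.max(d$stress$values)
  expect_true(all(diff(d$stress$values[pk:201]) < 0))
  # and is non-increasing right after the ramp for equal orders
  de <- generate_fm_dataset(fm_params(1, 1, 0.5, 0.5), eps0 = 1)
  expect_true(all(diff(de$stress$values[7:201]) < 0))
})

test_that("noise is scaled to the clean data's spread, is seeded, and level 0
           is the identity", {
  sc <- diffusion_scenario(alpha = 0.5, nx = 12, ny = 12, n_steps = 10)
  fld <- solve_tfde(sc)
  expect_identical(add_noise(fld, noise_spec(0, 1)), fld)
  n1 <- add_noise(fld, noise_spec(0.25, 42))
  n2 <- add_noise(fld, noise_spec(0.25, 42))
  expect_identical(n1$values, n2$values)
  n3 <- add_noise(fld, noise_spec(0.25, 43))
  expect_false(identical(n1$values, n3$values))
  # law of large numbers: empirical sd of the added noise ~ level * sd(clean)
  g <- time_grid(0, 1e-3, 1e5)
  clean <- scalar_series(sin(grid_times(g)), g)
  noisy <- add_noise(clean, noise_spec(0.25, 7))
  emp <- pop_sd_test(noisy$values - clean$values)
  expect_equal(emp, 0.25 * pop_sd_test(clean$values), tolerance = 0.01)
})

test_that("field and series round-trip through their CSV formats", {
  sc <- diffusion_scenario(alpha = 0.5, nx = 10, ny = 9, n_steps = 5)
  fld <- solve_tfde(sc)
  fp <- tempfile(fileext = ".csv")
  write_field_csv(fld, fp)
  back <- read_field_csv(fp)
  expect_equal(back$values, fld$values, tolerance = 1e-12)
  expect_equal(back$x, fld$x, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(fp, ".json"))
  expect_equal(meta$alpha_true, 0.5)
  unlink(c(fp, paste0(fp, ".json")))

  d <- generate_fm_dataset(fm_params(2, 0.8, 0.7, 0.2), eps0 = 1,
                           grid = time_grid(0, 0.05, 60))
  sp <- tempfile(fileext = ".csv")
  write_series_csv(d, sp, g_ref = seq_len(61))
  ds <- read_stress_strain_csv(sp)
  expect_equal(ds$stress$values, d$stress$values, tolerance = 1e-12)
  expect_equal(attr(ds, "g_ref"), seq_len(61))
  unlink(sp)
})

test_that("series reader rejects malformed input", {
  sp <- tempfile(fileext = ".csv")
  df <- data.frame(time = seq(0, 1, by = 0.1), stress = rnorm(11),
                   strain = rnorm(11))
  # shuffled rows: not strictly increasing
  utils::write.csv(df[sample(11), ], sp, row.names = FALSE)
  expect_error(read_stress_strain_csv(sp), "increasing")
  # non-uniform spacing
  df2 <- df; df2$time[5] <- df2$time[5] + 0.03
  utils::write.csv(df2, sp, row.names = FALSE)
  expect_error(read_stress_strain_csv(sp), "uniform")
  # missing column
  utils::write.csv(df[, 1:2], sp, row.names = FALSE)
  expect_error(read_stress_strain_csv(sp), "columns")
  unlink(sp)
})

test_that("thin_field keeps every k-th spatial point and the full history", {
  sc <- diffusion_scenario(alpha = 0.5, nx = 13, ny = 13, n_steps = 6)
  fld <- solve_tfde(sc)
  th <- thin_field(fld, 3L)
  expect_equal(dim(th$values), c(7, 5, 5))
  expect_equal(th$x, fld$x[c(1, 4, 7, 10, 13)])
  expect_equal(th$values[4, 2, 3], fld$values[4, 4, 7])
})
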