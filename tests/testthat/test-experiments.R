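# Tiny study conditions keep these end-to-end tests fast; the full benchmark
# conditions live in the acceptance suite.

tiny_plan <- function(levels = c(0, 0.25), seeds = 1L, iters = 250L) {
  noise_sweep_plan(
    alphas = 0.5, noise_levels = levels, seeds_per_cell = seeds,
    scenario = diffusion_scenario(alpha = 0.5, nx = 12, ny = 12, n_steps = 12),
    cfg = train_config(iterations = iters, seed = 1, log_every = 100),
    netspec_c = network_spec(3, 10, input_dim = 3),
    netspec_d = network_spec(2, 4, input_dim = 1),
    stride = 1L, base_seed = 7L)
}

test_that("noise sweep fills its grid, aggregates by median, and serializes a
           self-contained report", {
  plan <- tiny_plan(seeds = 2L)
  rep1 <- run_noise_sweep(plan)
  expect_equal(nrow(rep1$results), 4L)          # 1 alpha x 2 levels x 2 seeds
  expect_true(all(rep1$results$status == "ok"))
  expect_equal(dim(rep1$alpha_table), c(1L, 2L))
  expect_true(all(is.finite(rep1$alpha_table)))
  expect_equal(rep1$aggregation, "median")
  # median really is the per-cell median of replicates
  cell <- rep1$results[rep1$results$noise_level == 0.25, "alpha_hat"]
  expect_equal(unname(rep1$alpha_table[1, 2]), stats::median(cell))
  dir <- tempfile()
  write_sweep_report(rep1, dir)
  expect_true(all(file.exists(file.path(dir, c("results.csv", "alpha_table.csv",
                                               "d_err_table.csv",
                                               "report.json")))))
  back <- utils::read.csv(file.path(dir, "results.csv"))
  expect_equal(back$alpha_hat, rep1$results$alpha_hat, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("repeated sweeps with one plan are byte-identical and failures are
           contained per cell", {
  plan <- tiny_plan(levels = 0, seeds = 1L, iters = 150L)
  r1 <- run_noise_sweep(plan)
  r2 <- run_noise_sweep(plan)
  expect_identical(r1$results, r2$results)
  # a scenario whose fit must fail (constant field) is recorded, not fatal
  plan_bad <- plan
  plan_bad$scenario <- diffusion_scenario(alpha = 0.5, nx = 12, ny = 12,
                                          n_steps = 12,
                                          ic = function(x, y) 0 * x)
  rb <- run_noise_sweep(plan_bad)
  expect_true(all(rb$results$status == "failed"))
  expect_match(rb$results$message[1], "constant")
})

test_that("relaxation workflow ingests CSV, writes artifacts, and enforces its
           input contract", {
  p <- fm_params(2, 0.8, 0.7, 0.2)
  d <- generate_fm_dataset(p, eps0 = 1, grid = time_grid(0, 0.1, 60))
  tt <- grid_times(d$grid)
  sp <- tempfile(fileext = ".csv")
  write_series_csv(d, sp, g_ref = c(NA, relaxation_modulus(p, tt[-1])))
  out <- tempfile()
  res <- predict_relaxation_workflow(
    sp, cfg = train_config(iterations = 300, seed = 4, log_every = 100),
    ramp_steps = 5L, out_dir = out)
  expect_true(is.finite(res$g_rel_err))
  expect_true(all(file.exists(file.path(out, c("parameters.json",
                                               "gt_curve.csv",
                                               "loss_trace.csv")))))
  pj <- jsonlite::read_json(file.path(out, "parameters.json"))
  expect_true(pj$kappa > 0 && pj$mu > 0 && pj$mu < 1)
  expect_equal(nrow(utils::read.csv(file.path(out, "gt_curve.csv"))),
               sum(tt > 0.5))
  unlink(c(sp, out), recursive = TRUE)

  # zero-stress input violates the sigma > 0 precondition
  sp2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = tt, stress = 0,
                              strain = d$strain$values), sp2,
                   row.names = FALSE)
  expect_error(predict_relaxation_workflow(sp2), "constant")
  unlink(sp2)
})

test_that("the command-line interface validates input and writes artifacts", {
  skip_if(Sys.which("Rscript") == "", "Rscript not on PATH")
  cli <- system.file("cli", "fracpinn", package = "fracpinn")
  skip_if(cli == "", "installed CLI script not found")
  run_cli <- function(...) {
    suppressWarnings(system2("Rscript", c(cli, ...), stdout = TRUE,
                             stderr = TRUE))
  }
  # unknown command -> exit 2
  out <- run_cli("frobnicate")
  expect_equal(attr(out, "status") %||% 0L, 2L)
  # simulate-maxwell writes a readable series
  od <- tempfile()
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("maxwell:", "  dt: 0.1", "  n_steps: 50"), cfg)
  out <- run_cli("simulate-maxwell", "--config", cfg, "--seed", "3",
                 "--out", od)
  expect_null(attr(out, "status"))
  series <- read_stress_strain_csv(file.path(od, "series.csv"))
  expect_equal(series$grid$n_steps, 50L)
  # fit-maxwell on a malformed file -> exit 2
  bad <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  out <- run_cli("fit-maxwell", "--in", bad, "--out", od)
  expect_equal(attr(out, "status") %||% 0L, 2L)
  unlink(c(od, cfg, bad), recursive = TRUE)
})
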