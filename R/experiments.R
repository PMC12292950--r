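#' Plan for a noise-robustness sweep
#'
#' Describes the full factorial experiment over true fractional orders and
#' Gaussian noise levels: for each cell, the benchmark field is generated with
#' that order, corrupted at that level, and fitted; recovered orders and
#' coefficient-curve errors are recorded per seed.
#'
#' @param alphas True orders (default `c(0.3, 0.5, 0.7)`).
#' @param noise_levels Noise levels as fractions of the clean field's standard
#'   deviation (default `c(0, 0.05, 0.10, 0.15, 0.20, 0.25)`).
#' @param seeds_per_cell Replicates per cell (default 3).
#' @param scenario Template [diffusion_scenario()]; its `alpha` is overridden
#'   per cell.
#' @param cfg A [train_config()].
#' @param netspec_c,netspec_d Surrogate architectures, as in
#'   [fit_anomalous_diffusion()].
#' @param stride Spatial thinning applied to the generated field before
#'   fitting (see [thin_field()]).
#' @param base_seed Seed from which all cell seeds are derived.
#' @return An object of class `"noise_sweep_plan"`.
#' @export
noise_sweep_plan <- function(alphas = c(0.3, 0.5, 0.7),
                             noise_levels = c(0, 0.05, 0.10, 0.15, 0.20, 0.25),
                             seeds_per_cell = 3L,
                             scenario = diffusion_scenario(),
                             cfg = train_config(),
                             netspec_c = network_spec(4, 16, input_dim = 3),
                             netspec_d = network_spec(2, 4, input_dim = 1),
                             stride = 3L,
                             base_seed = 1L) {
  if (length(alphas) < 1L || length(noise_levels) < 1L)
    stop("`alphas` and `noise_levels` must be non-empty", call. = FALSE)
  for (a in alphas) check_order(a)
  if (any(noise_levels < 0) || any(noise_levels > 1))
    stop("`noise_levels` must lie in [0, 1]", call. = FALSE)
  seeds_per_cell <- as.integer(seeds_per_cell)
  if (seeds_per_cell < 1L) stop("`seeds_per_cell` must be >= 1", call. = FALSE)
  structure(list(alphas = alphas, noise_levels = noise_levels,
                 seeds_per_cell = seeds_per_cell, scenario = scenario,
                 cfg = cfg, netspec_c = netspec_c, netspec_d = netspec_d,
                 stride = as.integer(stride),
                 base_seed = as.integer(base_seed)),
            class = "noise_sweep_plan")
}

#' Run a noise-robustness sweep
#'
#' Executes every `(alpha_true, noise_level, seed)` cell of the plan:
#' generate, corrupt, thin, fit, record. Fit failures are caught and the cell
#' is marked failed rather than aborting the sweep. Cell seeds are a pure
#' function of the plan, so re-running a plan reproduces the report exactly,
#' independent of execution order.
#'
#' @param plan A [noise_sweep_plan()].
#' @param verbose Print one line per finished cell.
#' @return An object of class `"sweep_report"`: `$results` has one row per
#'   replicate (recovered order, relative errors, final losses, seed,
#'   status); `$alpha_table` holds the median recovered order per cell in a
#'   wide orders-by-noise layout, `$d_err_table` the corresponding median
#'   coefficient-curve errors; the aggregation rule is recorded in
#'   `$aggregation`.
#' @export
run_noise_sweep <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "noise_sweep_plan"))
  rows <- list()
  cell_i <- 0L
  # fields are cached per (alpha, noise, replicate) seed; fits per fit seed
  for (a in plan$alphas) {
    sc <- plan$scenario
    sc$alpha <- a
    clean <- solve_tfde(sc)
    for (lev in plan$noise_levels) {
      for (r in seq_len(plan$seeds_per_cell)) {
        cell_i <- cell_i + 1L
        noise_seed <- plan$base_seed + 7919L * cell_i
        fit_seed <- plan$base_seed + 104729L + cell_i
        row <- list(alpha_true = a, noise_level = lev, replicate = r,
                    noise_seed = noise_seed, fit_seed = fit_seed,
                    alpha_hat = NA_real_, alpha_rel_err = NA_real_,
                    d_rel_err = NA_real_, data_loss = NA_real_,
                    consistency_loss = NA_real_, status = "ok",
                    message = "")
        res <- tryCatch({
          noisy <- add_noise(clean, noise_spec(lev, seed = noise_seed))
          train <- thin_field(noisy, plan$stride)
          cfg <- plan$cfg
          cfg$seed <- fit_seed
          fit <- fit_anomalous_diffusion(train, plan$netspec_c,
                                         plan$netspec_d, cfg,
                                         truth = list(alpha = a, law = sc$law))
          row$alpha_hat <- fit$alpha
          row$alpha_rel_err <- fit$rel_err$alpha
          row$d_rel_err <- fit$rel_err$dcoef
          row$data_loss <- fit$losses$data
          row$consistency_loss <- fit$losses$consistency
          row
        }, error = function(e) {
          row$status <- "failed"
          row$message <- conditionMessage(e)
          row
        })
        rows[[cell_i]] <- res
        if (verbose)
          message(sprintf("alpha %.2f noise %4.0f%% rep %d: alpha_hat %s [%s]",
                          a, lev * 100, r,
                          ifelse(is.na(res$alpha_hat), "-",
                                 sprintf("%.4f", res$alpha_hat)),
                          res$status))
      }
    }
  }
  results <- do.call(rbind, lapply(rows, as.data.frame))
  agg <- function(col) {
    tab <- matrix(NA_real_, length(plan$alphas), length(plan$noise_levels),
                  dimnames = list(paste0("alpha_", plan$alphas),
                                  paste0("noise_", plan$noise_levels)))
    for (i in seq_along(plan$alphas))
      for (j in seq_along(plan$noise_levels)) {
        v <- results[results$alpha_true == plan$alphas[i] &
                     results$noise_level == plan$noise_levels[j] &
                     results$status == "ok", col]
        if (length(v)) tab[i, j] <- stats::median(v)
      }
    tab
  }
  structure(list(results = results,
                 alpha_table = agg("alpha_hat"),
                 d_err_table = agg("d_rel_err"),
                 aggregation = "median",
                 plan = plan),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("<sweep_report> median recovered fractional orders:\n")
  print(round(x$alpha_table, 4))
  cat("median coefficient-curve relative errors:\n")
  print(round(x$d_err_table, 4))
  nf <- sum(x$results$status != "ok")
  if (nf) cat(sprintf("  (%d failed cells)\n", nf))
  invisible(x)
}

#' Serialize a sweep report
#'
#' Writes `results.csv` (all replicates), `alpha_table.csv` and
#' `d_err_table.csv` (the aggregated grids) plus `report.json` with the plan
#' summary — everything needed to regenerate tables and figures without the R
#' session.
#'
#' @param report A `"sweep_report"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sweep_report <- function(report, dir) {
  stopifnot(inherits(report, "sweep_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$alpha_table),
                   file.path(dir, "alpha_table.csv"))
  utils::write.csv(as.data.frame(report$d_err_table),
                   file.path(dir, "d_err_table.csv"))
  pl <- report$plan
  jsonlite::write_json(
    list(alphas = pl$alphas, noise_levels = pl$noise_levels,
         seeds_per_cell = pl$seeds_per_cell, base_seed = pl$base_seed,
         stride = pl$stride, iterations = pl$cfg$iterations,
         aggregation = report$aggregation),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' End-to-end relaxation-modulus prediction from a rheology CSV
#'
#' Reads a `time,stress,strain` CSV (see [read_stress_strain_csv()]), fits the
#' fractional Maxwell model with [fit_fractional_maxwell()], predicts the
#' relaxation modulus from the learned parameters, and (when a `G_ref` column
#' or reference vector is available) reports the relative curve error.
#' Optionally writes `parameters.json`, `gt_curve.csv` and `loss_trace.csv`.
#'
#' @param series_path Path to the input CSV.
#' @param cfg A [train_config()].
#' @param netspec Surrogate architecture.
#' @param ramp_steps Initial grid intervals excluded from the modulus-error
#'   window (loading ramp).
#' @param g_ref Optional reference modulus values on the data grid (overrides
#'   a `G_ref` column).
#' @param out_dir Optional output directory.
#' @return A list with the fit, the predicted modulus curve (data frame
#'   `t, G`), and `g_rel_err` (or `NA`).
#' @export
predict_relaxation_workflow <- function(series_path,
                                        cfg = train_config(),
                                        netspec = network_spec(2, 20, input_dim = 1),
                                        ramp_steps = 5L,
                                        g_ref = NULL,
                                        out_dir = NULL) {
  data <- read_stress_strain_csv(series_path)
  if (is.null(g_ref)) g_ref <- attr(data, "g_ref")
  fit <- fit_fractional_maxwell(data, netspec = netspec, cfg = cfg,
                                ramp_steps = ramp_steps)
  tt <- grid_times(data$grid)
  keep <- tt > ramp_steps * data$grid$dt + 1e-12
  t_eval <- tt[keep]
  g_curve <- data.frame(t = t_eval, G = fit$gt_fn(t_eval))
  g_rel_err <- NA_real_
  if (!is.null(g_ref)) {
    if (length(g_ref) != length(tt))
      stop("`g_ref` must match the data grid", call. = FALSE)
    g_rel_err <- relative_error(g_curve$G, g_ref[keep])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fm <- fit$fm
    jsonlite::write_json(
      list(kappa = fm$kappa, eta = fm$eta, mu = fm$mu, nu = fm$nu,
           g_rel_err = g_rel_err, iterations = cfg$iterations,
           seed = cfg$seed),
      file.path(out_dir, "parameters.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(g_curve, file.path(out_dir, "gt_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$trace, file.path(out_dir, "loss_trace.csv"),
                     row.names = FALSE)
  }
  list(fit = fit, g_curve = g_curve, g_rel_err = g_rel_err)
}
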