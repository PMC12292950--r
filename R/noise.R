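#' Gaussian noise specification
#'
#' Noise is scaled to the data: samples receive i.i.d. Gaussian perturbations
#' with standard deviation `level` times the population standard deviation of
#' the clean data (a global convention, not per-point percent of signal; it
#' matches the variance scaling of the losses).
#'
#' @param level Noise level as a fraction of the clean data's standard
#'   deviation (0.25 means 25 percent).
#' @param seed Integer seed; two applications with the same seed are
#'   identical.
#' @param kind Only `"gaussian"` is supported.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(level, seed = 1L, kind = "gaussian") {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level < 0)
    stop("`level` must be a single number >= 0", call. = FALSE)
  kind <- match.arg(kind, "gaussian")
  structure(list(level = level, seed = as.integer(seed), kind = kind),
            class = "noise_spec")
}

# run expr with a private RNG state, restoring the caller's state afterwards
with_private_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Corrupt reference data with Gaussian noise
#'
#' Adds `Normal(0, (level * sd_ref)^2)` noise i.i.d. per sample, where
#' `sd_ref` is the population standard deviation of the clean data. Works on
#' [st_field()], [scalar_series()] and [stress_strain_series()] objects (for
#' the latter, stress and strain are perturbed by their own scales from one
#' seeded stream). The returned object's stored scale (`sigma_c` / `sigma`) is
#' recomputed from the noisy samples, since that is what the losses of a
#' subsequent fit can observe.
#'
#' @param x The clean data object.
#' @param spec A [noise_spec()].
#' @return An object of the same class as `x`.
#' @export
add_noise <- function(x, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$level == 0) return(x)
  UseMethod("add_noise")
}

#' @export
add_noise.st_field <- function(x, spec) {
  sd_ref <- pop_sd(x$values)
  noisy <- with_private_seed(spec$seed, {
    x$values + stats::rnorm(length(x$values), sd = spec$level * sd_ref)
  })
  st_field(noisy, x$grid, x$x, x$y, scenario = x$scenario)
}

#' @export
add_noise.scalar_series <- function(x, spec) {
  sd_ref <- pop_sd(x$values)
  noisy <- with_private_seed(spec$seed, {
    x$values + stats::rnorm(length(x$values), sd = spec$level * sd_ref)
  })
  scalar_series(noisy, x$grid)
}

#' @export
add_noise.stress_strain_series <- function(x, spec) {
  noisy <- with_private_seed(spec$seed, {
    s1 <- x$stress$values +
      stats::rnorm(length(x$stress$values),
                   sd = spec$level * pop_sd(x$stress$values))
    s2 <- x$strain$values +
      stats::rnorm(length(x$strain$values),
                   sd = spec$level * pop_sd(x$strain$values))
    list(s1, s2)
  })
  stress_strain_series(stress = noisy[[1]], strain = noisy[[2]],
                       grid = x$grid, eps0 = x$eps0)
}
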