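#' Read and write concentration fields and rheology series
#'
#' Fields are exchanged as long-format CSV with columns `t,x,y,c` plus a JSON
#' sidecar (`<path>.json`) holding grid metadata; rheology series as CSV with
#' header `time,stress,strain` and an optional `G_ref` column. All readers
#' validate that the time column forms a uniform, strictly increasing grid
#' (resampling is out of scope) and reject malformed input.
#'
#' @param field An [st_field()].
#' @param path Output/input file path.
#' @return `write_*` return `path` invisibly; readers return the parsed
#'   object.
#' @name field_io
NULL

#' @rdname field_io
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "st_field"))
  tt <- grid_times(field$grid)
  d <- dim(field$values)
  df <- data.frame(
    t = rep(tt, times = d[2] * d[3]),
    x = rep(rep(field$x, each = d[1]), times = d[3]),
    y = rep(field$y, each = d[1] * d[2]),
    c = as.vector(field$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(t0 = field$grid$t0, dt = field$grid$dt,
               n_steps = field$grid$n_steps,
               x = field$x, y = field$y, sigma_c = field$sigma_c)
  if (!is.null(field$scenario))
    meta$alpha_true <- field$scenario$alpha
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname field_io
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "c")
  if (!all(need %in% names(df)))
    stop("field CSV must have columns t, x, y, c", call. = FALSE)
  tt <- sort(unique(df$t)); xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  check_uniform(tt, "t")
  if (nrow(df) != length(tt) * length(xs) * length(ys))
    stop("field CSV does not cover a full (t, x, y) tensor grid", call. = FALSE)
  ord <- order(df$y, df$x, df$t)
  vals <- array(df$c[ord], dim = c(length(tt), length(xs), length(ys)))
  grid <- time_grid(tt[1], tt[2] - tt[1], length(tt) - 1L)
  st_field(vals, grid, xs, ys)
}

check_uniform <- function(v, name) {
  if (length(v) < 2L)
    stop(sprintf("column `%s` must hold at least 2 distinct points", name),
         call. = FALSE)
  d <- diff(v)
  if (any(d <= 0) || diff(range(d)) > 1e-8 * max(abs(d)))
    stop(sprintf("column `%s` must form a uniform, strictly increasing grid",
                 name), call. = FALSE)
  invisible(v)
}

#' @rdname field_io
#' @param series A [stress_strain_series()].
#' @param g_ref Optional reference relaxation modulus values written as a
#'   `G_ref` column.
#' @export
write_series_csv <- function(series, path, g_ref = NULL) {
  stopifnot(inherits(series, "stress_strain_series"))
  df <- data.frame(time = grid_times(series$grid),
                   stress = series$stress$values,
                   strain = series$strain$values)
  if (!is.null(g_ref)) df$G_ref <- g_ref
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname field_io
#' @export
read_stress_strain_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "stress", "strain")
  if (!all(need %in% names(df)))
    stop("series CSV must have columns time, stress, strain", call. = FALSE)
  if (anyNA(df[need]))
    stop("series CSV contains missing values", call. = FALSE)
  tt <- df$time
  if (is.unsorted(tt, strictly = TRUE))
    stop("`time` must be strictly increasing (rows in order, no resampling)",
         call. = FALSE)
  check_uniform(tt, "time")
  grid <- time_grid(tt[1], tt[2] - tt[1], length(tt) - 1L)
  out <- stress_strain_series(df$stress, df$strain, grid)
  if ("G_ref" %in% names(df)) attr(out, "g_ref") <- df$G_ref
  out
}
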