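#' Two-parameter Mittag-Leffler function
#'
#' Evaluates \eqn{E_{a,b}(z) = \sum_{n \ge 0} z^n / \Gamma(an + b)} for real
#' `z`, to at least 8 significant digits over the argument range arising in
#' fractional relaxation moduli (`z = -t^mu / eta`, down to `z = -1e6`).
#'
#' Three evaluation regimes are combined:
#' \itemize{
#'   \item the truncated power series with term-magnitude stopping, wherever it
#'     is free of catastrophic cancellation (all `z >= 0`; small `|z|`; and
#'     `a >= 1` with moderate `|z|`);
#'   \item for `z < 0` and `0 < a < 1`, the real integral representation of
#'     Gorenflo, Loutchko and Luchko evaluated by adaptive quadrature (after
#'     reducing `b` below `1 + a` with the recurrence
#'     \eqn{E_{a,b}(z) = (E_{a,b-a}(z) - 1/\Gamma(b-a)) / z});
#'   \item for `a = 1`, the Kummer-transformed confluent hypergeometric series,
#'     which has no cancellation for `z < 0`.
#' }
#' Reciprocals of the gamma function at its poles are taken as zero.
#'
#' @param a First parameter, `a > 0`.
#' @param b Second parameter, real (default 1).
#' @param z Real argument (vectorized).
#' @return `E_{a,b}(z)`, same length as `z`.
#' @examples
#' mittag_leffler(1, 1, 1)        # exp(1)
#' mittag_leffler(2, 1, -4)       # cos(2)
#' @export
mittag_leffler <- function(a, b = 1, z) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("`b` must be a single finite number", call. = FALSE)
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z)))
    stop("`z` must be finite and real", call. = FALSE)
  vapply(as.numeric(z), ml_scalar, numeric(1), a = a, b = b)
}

ml_scalar <- function(a, b, z) {
  if (z == 0) return(rgamma_safe(b))
  if (a == 1) return(ml_a1(b, z))
  if (z < 0 && a < 1) {
    if (abs(z) <= 2) return(ml_series(a, b, z))
    return(ml_gll(a, b, z))
  }
  ml_series(a, b, z)
}

# 1 / Gamma(x), zero at the poles of Gamma
rgamma_safe <- function(x) {
  if (x <= 0 && x == round(x)) return(0)
  g <- gamma(x)
  if (!is.finite(g)) return(0)
  1 / g
}

# power series with term-magnitude stopping and a cancellation guard
ml_series <- function(a, b, z, max_terms = 5000L) {
  s <- 0
  max_abs <- 0
  az <- abs(z)
  lgz <- log(az)
  tail_from <- if (az > 1) az^(1 / a) else 0   # past the largest term
  small_run <- 0L
  for (n in 0:max_terms) {
    g <- a * n + b
    if (g > 0) {
      lt <- n * lgz - lgamma(g)
      if (lt > 700) {
        stop(sprintf(paste0("mittag_leffler: power series overflows for a = %g,",
                            " b = %g, z = %g; argument outside supported range"),
                     a, b, z), call. = FALSE)
      }
      term <- exp(lt) * (if (z < 0 && n %% 2L == 1L) -1 else 1)
    } else {
      term <- z^n * rgamma_safe(g)
    }
    s <- s + term
    max_abs <- max(max_abs, abs(term))
    if (n > 5L && abs(term) <= 1e-16 * max(abs(s), 1e-300) && g > tail_from) {
      small_run <- small_run + 1L
      if (small_run >= 3L) break
    } else small_run <- 0L
    if (n == max_terms)
      stop("mittag_leffler: power series did not converge", call. = FALSE)
  }
  if (max_abs > 1e13 * max(abs(s), 1e-300))
    stop(sprintf(paste0("mittag_leffler: catastrophic cancellation in the ",
                        "series for a = %g, b = %g, z = %g"), a, b, z),
         call. = FALSE)
  s
}

# a = 1: E_{1,b}(z) = 1F1(1; b; z) / Gamma(b); for z < 0 use the Kummer
# transform M(1, b, z) = e^z M(b - 1, b, -z), whose series has positive terms.
ml_a1 <- function(b, z) {
  if (b == 1) return(exp(z))
  if (z > 0 || (b < 1 && abs(z) <= 2)) return(ml_series(1, b, z))
  if (b < 1) {
    # raise b into the Kummer-safe zone: E_{a,b} = z E_{a,b+a} + 1/Gamma(b)
    return(z * ml_a1(b + 1, z) + rgamma_safe(b))
  }
  if (z < -700) {
    # exponential part underflows; algebraic tail dominates
    return(ml_asymptotic(1, b, z))
  }
  x <- -z
  term <- 1
  s <- 1
  for (k in 1:100000) {
    term <- term * x / k
    tk <- term * (b - 1) / (b - 1 + k)
    s <- s + tk
    if (k > 5 && tk < 1e-17 * s && k > x) break
  }
  exp(z + log(s)) / gamma(b)
}

# leading asymptotic expansion for z -> -Inf:  -sum_{n>=1} z^{-n}/Gamma(b - a n)
ml_asymptotic <- function(a, b, z, N = 60L) {
  n <- 1:N
  s <- 0
  zi <- 1
  best <- Inf
  acc <- 0
  for (k in n) {
    zi <- zi / z
    term <- -zi * rgamma_safe(b - a * k)
    if (abs(term) > best) break      # divergent tail: stop at smallest term
    best <- abs(term)
    acc <- acc + term
  }
  acc
}

# Gorenflo-Loutchko-Luchko integral representation for 0 < a < 1, z < 0.
# Valid directly for b <= 1 + a; larger b is reduced by the recurrence
# E_{a,b}(z) = (E_{a,b-a}(z) - 1/Gamma(b-a)) / z.
ml_gll <- function(a, b, z) {
  # reduce b away from the b = 1 + a boundary, where the representation
  # degenerates; each step lowers b by a
  if (b > 1 + a - min(a, 0.2) / 2) {
    return((ml_gll(a, b - a, z) - rgamma_safe(b - a)) / z)
  }
  s1b <- sin(pi * (1 - b))
  s1ba <- sin(pi * (1 - b + a))
  cpa <- cos(pi * a)
  # substituted r = u^a: integrand is smooth with exponential decay in u
  K <- function(u) {
    ua <- u^a
    num <- ua * s1b - z * s1ba
    den <- ua^2 - 2 * ua * z * cpa + z^2
    (1 / pi) * u^(a - b) * exp(-u) * num / den
  }
  # near u = 0 the integrand behaves like u^{a-b} (or u^{2a-b} when the z-term
  # of the numerator vanishes, i.e. b = 1 + a); substituting u = w^{1/p} with
  # p = 1 + that exponent makes it bounded there
  e0 <- a - b
  if (abs(s1ba) < 1e-13) e0 <- e0 + a
  p <- 1 + e0
  if (p <= 0) p <- 1e-2   # unreachable for b <= 1 + a; keep quadrature defined
  K0 <- function(w) K(w^(1 / p)) * w^(1 / p - 1) / p
  i1 <- stats::integrate(K0, 0, 1, rel.tol = 1e-11, abs.tol = 0,
                         subdivisions = 500L)
  i2 <- stats::integrate(K, 1, 60, rel.tol = 1e-11, abs.tol = 0,
                         subdivisions = 500L)
  if (i1$message != "OK" || i2$message != "OK")
    stop("mittag_leffler: quadrature failed", call. = FALSE)
  i1$value + i2$value
}
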