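# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The training graphs here are small (tens of nodes) while the node values are
# large matrices, so a plain tape of closures is efficient: all heavy work is
# BLAS-level matrix arithmetic. Nodes are integer indices into the tape; each
# op records its parents and a backward closure mapping the output gradient to
# parent-gradient contributions. Gradients have the same shape as values.
#
# Internal API (not exported): tp_new, tp_var, tp_value, tp_backward and the
# tp_* operators used by the PINN engines. Every operator is covered by
# finite-difference gradient checks in the test suite.

tp_new <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$vals <- list()
  e$bwd <- list()
  e$pars <- list()
  e
}

tp_node <- function(tp, val, parents = integer(), bwd = NULL) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- val
  tp$pars[[tp$n]] <- parents
  tp$bwd[[tp$n]] <- bwd
  tp$n
}

# leaf holding a value (parameter or constant)
tp_var <- function(tp, x) tp_node(tp, x)

tp_value <- function(tp, id) tp$vals[[id]]

# backward pass from scalar node `id`; returns list of gradients per node id
tp_backward <- function(tp, id) {
  grads <- vector("list", tp$n)
  v <- tp$vals[[id]]
  grads[[id]] <- if (is.matrix(v)) matrix(1, nrow(v), ncol(v)) else 1
  for (i in seq(id, 1L)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(tp$bwd[[i]])) next
    contr <- tp$bwd[[i]](g)
    ps <- tp$pars[[i]]
    for (k in seq_along(ps)) {
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) contr[[k]]
                    else grads[[p]] + contr[[k]]
    }
  }
  grads
}

## ---- primitive operators ----------------------------------------------

tp_mm <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_node(tp, A %*% B, c(a, b),
          function(g) list(tcrossprod(g, B), crossprod(A, g)))
}

# add a bias row vector to every row of a matrix
tp_addrow <- function(tp, a, bias) {
  force(a); force(bias)
  A <- tp$vals[[a]]; v <- tp$vals[[bias]]
  tp_node(tp, A + rep(v, each = nrow(A)), c(a, bias),
          function(g) list(g, matrix(colSums(g), 1)))
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_node(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b),
          function(g) list(g, g))
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_node(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b),
          function(g) list(g, -g))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_node(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

# multiply a matrix node by a scalar node
tp_smul <- function(tp, a, s) {
  force(a); force(s)
  A <- tp$vals[[a]]; sv <- as.numeric(tp$vals[[s]])
  tp_node(tp, A * sv, c(a, s),
          function(g) list(g * sv, sum(g * A)))
}

tp_cmul <- function(tp, a, const) {
  force(a)
  tp_node(tp, tp$vals[[a]] * const, a, function(g) list(g * const))
}

tp_cadd <- function(tp, a, const) {
  force(a)
  tp_node(tp, tp$vals[[a]] + const, a, function(g) list(g))
}

tp_square <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  tp_node(tp, A * A, a, function(g) list(2 * g * A))
}

tp_mean <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  tp_node(tp, mean(A), a,
          function(g) list(array(as.numeric(g) / length(A), dim(A) %||% length(A))))
}

tp_sigmoid <- function(tp, a) {
  force(a)
  s <- 1 / (1 + exp(-tp$vals[[a]]))
  tp_node(tp, s, a, function(g) list(g * s * (1 - s)))
}

tp_swish <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  s <- 1 / (1 + exp(-A))
  tp_node(tp, A * s, a, function(g) list(g * (s + A * s * (1 - s))))
}

tp_softplus <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  if (!is.matrix(A)) A <- as.matrix(A)
  fw <- .softplus_fwd(A)
  s <- fw[[2]]
  tp_node(tp, fw[[1]], a, function(g) list(g * s))
}

tp_reshape <- function(tp, a, dims) {
  force(a)
  A <- tp$vals[[a]]
  od <- dim(A) %||% length(A)
  v <- A; dim(v) <- dims
  tp_node(tp, v, a, function(g) { dim(g) <- od; list(g) })
}

# subset rows/columns of a matrix (NULL keeps all); backward scatters
tp_subset <- function(tp, a, rows = NULL, cols = NULL) {
  force(a)
  A <- tp$vals[[a]]
  r <- rows %||% seq_len(nrow(A)); cl <- cols %||% seq_len(ncol(A))
  tp_node(tp, A[r, cl, drop = FALSE], a, function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    G[r, cl] <- g
    list(G)
  })
}

# constant (possibly sparse) matrix times node: M %*% A
tp_spmm <- function(tp, M, a) {
  force(a)
  A <- tp$vals[[a]]
  Mt <- Matrix::t(M)
  tp_node(tp, as.matrix(M %*% A), a,
          function(g) list(as.matrix(Mt %*% g)))
}

# fused dense layer: swish(X %*% W + b) (or linear); one node instead of
# three keeps allocation traffic down on the large training matrices
tp_dense <- function(tp, x, w, b, act = "swish") {
  force(x); force(w); force(b)
  X <- tp$vals[[x]]; W <- tp$vals[[w]]; bv <- tp$vals[[b]]
  Z <- X %*% W
  if (act == "linear") {
    Z <- Z + rep(bv, each = nrow(Z))
    return(tp_node(tp, Z, c(x, w, b), function(g) {
      list(tcrossprod(g, W), crossprod(X, g), matrix(colSums(g), 1))
    }))
  }
  fw <- .swish_fwd(Z, as.numeric(bv))
  Zb <- fw[[2]]; S <- fw[[3]]
  tp_node(tp, fw[[1]], c(x, w, b), function(g) {
    gz <- .swish_bwd(g, Zb, S)
    list(tcrossprod(gz, W), crossprod(X, gz), matrix(colSums(gz), 1))
  })
}

## ---- fractional-calculus operators (alpha-differentiable) ---------------

# Gamma(2 - alpha) * dt^alpha as a scalar node
tp_prefactor <- function(tp, alpha, dt) {
  force(alpha)
  av <- as.numeric(tp$vals[[alpha]])
  v <- gamma(2 - av) * dt^av
  dv <- v * (-digamma(2 - av) + log(dt))
  tp_node(tp, v, alpha, function(g) list(sum(g) * dv))
}

# history operator: C (nspace x (n+1)) %*% t(H(alpha)) -> (nspace x n)
tp_history <- function(tp, cmat, alpha, n) {
  force(cmat); force(alpha)
  av <- as.numeric(tp$vals[[alpha]])
  b <- l1_weights(av, n)
  db <- l1_weights_dalpha(av, n)
  H <- history_matrix_from_b(b, n)
  dH <- history_matrix_from_b(db, n)
  Cm <- tp$vals[[cmat]]
  tp_node(tp, tcrossprod(Cm, H), c(cmat, alpha),
          function(g) list(g %*% H, sum(g * tcrossprod(Cm, dH))))
}

# full L1 derivative operator applied to a column-vector series node,
# including the 1 / (Gamma(2 - alpha) dt^alpha) prefactor
tp_caputo <- function(tp, series, alpha, dt) {
  force(series); force(alpha)
  av <- as.numeric(tp$vals[[alpha]])
  sv <- tp$vals[[series]]
  n <- length(sv) - 1L
  b <- l1_weights(av, n - 1L)
  db <- l1_weights_dalpha(av, n - 1L)
  M <- l1_diff_matrix(b, n)
  dM <- l1_diff_matrix(db, n)
  pref <- 1 / (gamma(2 - av) * dt^av)
  dpref <- pref * (digamma(2 - av) - log(dt))
  W <- M * pref
  dW <- dM * pref + M * dpref
  tp_node(tp, W %*% sv, c(series, alpha),
          function(g) list(crossprod(W, g), sum(g * (dW %*% sv))))
}

# unnormalized L1 difference matrix (no prefactor) from a weight vector:
# row r holds +b_j at column r+2-j and -b_j at column r+1-j, j = 1..r.
# Built once per training iteration per order, so the Toeplitz fill indices
# are cached per matrix size.
.op_cache <- new.env(parent = emptyenv())

l1_fill_idx <- function(n) {
  key <- paste0("l1_", n)
  cached <- .op_cache[[key]]
  if (!is.null(cached)) return(cached)
  ro <- .row(c(n, n + 1L)); co <- .col(c(n, n + 1L))
  s1 <- which(co >= 2L & co <= ro + 1L)
  s2 <- which(co <= ro)
  out <- list(i1 = s1, b1 = (ro - co + 2L)[s1],
              i2 = s2, b2 = (ro - co + 1L)[s2])
  .op_cache[[key]] <- out
  out
}

l1_diff_matrix <- function(b, n) {
  ix <- l1_fill_idx(n)
  W <- numeric(n * (n + 1L))
  W[ix$i1] <- b[ix$b1]
  W[ix$i2] <- W[ix$i2] - b[ix$b2]
  dim(W) <- c(n, n + 1L)
  W
}

`%||%` <- function(a, b) if (is.null(a)) b else a
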