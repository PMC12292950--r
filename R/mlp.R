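#' Fully connected network specification
#'
#' Architecture of one multilayer perceptron surrogate: `n_layers` hidden
#' layers of `width` neurons with the swish activation
#' (\eqn{x\,\sigma(x)}), a linear output layer, Glorot-normal initial
#' weights drawn from `init_seed`. Defaults mirror the surrogates used in the
#' inverse solvers: 4 x 16 for the concentration network, 2 x 4 for the
#' diffusion-coefficient network, 2 x 20 for the stress and strain networks.
#'
#' @param n_layers Number of hidden layers, `>= 1`.
#' @param width Neurons per hidden layer, `>= 1`.
#' @param activation Activation name; only `"swish"` is supported.
#' @param input_dim,output_dim Input/output dimension.
#' @param init_seed Integer seed for weight initialization.
#' @return An object of class `"network_spec"`.
#' @export
network_spec <- function(n_layers, width, activation = "swish",
                         input_dim = 1L, output_dim = 1L, init_seed = 1L) {
  n_layers <- as.integer(n_layers); width <- as.integer(width)
  if (n_layers < 1L || width < 1L)
    stop("`n_layers` and `width` must be >= 1", call. = FALSE)
  activation <- match.arg(activation, "swish")
  structure(list(n_layers = n_layers, width = width, activation = activation,
                 input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 init_seed = as.integer(init_seed)),
            class = "network_spec")
}

# initialize weights/biases (Glorot normal, biases zero); returns a flat list
# W1, b1, W2, b2, ... ending with the linear output layer
mlp_init <- function(spec, seed = spec$init_seed) {
  dims <- c(spec$input_dim, rep(spec$width, spec$n_layers), spec$output_dim)
  with_private_seed(seed, {
    params <- list()
    for (l in seq_len(length(dims) - 1L)) {
      fi <- dims[l]; fo <- dims[l + 1L]
      params[[2L * l - 1L]] <- matrix(stats::rnorm(fi * fo, sd = sqrt(2 / (fi + fo))),
                                      fi, fo)
      params[[2L * l]] <- matrix(0, 1, fo)
    }
    params
  })
}

# forward pass on the tape; `xid` is a node holding the (N x input_dim) input,
# `pids` the parameter node ids in mlp_init order. Linear output layer.
mlp_forward <- function(tp, pids, xid) {
  nl <- length(pids) / 2L
  h <- xid
  for (l in seq_len(nl)) {
    h <- tp_dense(tp, h, pids[[2L * l - 1L]], pids[[2L * l]],
                  act = if (l < nl) "swish" else "linear")
  }
  h
}

# plain numeric forward pass (no tape), for decoded surrogates
mlp_eval <- function(params, X) {
  nl <- length(params) / 2L
  h <- X
  for (l in seq_len(nl)) {
    z <- h %*% params[[2L * l - 1L]] + rep(params[[2L * l]], each = nrow(h))
    if (l < nl) {
      s <- 1 / (1 + exp(-z))
      h <- z * s
    } else h <- z
  }
  h
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))
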