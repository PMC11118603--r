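# GRU parameter initialization and forward glue around the compiled core.

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# random orthogonal matrix (QR with sign-corrected R diagonal); the
# standard initializer for recurrent kernels — it preserves hidden-state
# magnitude across the 20 timesteps where a sub-unit-spectral-radius
# random matrix would wash it out
orthogonal_init <- function(n) {
  qr_dec <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_dec)
  q * sign(diag(qr.R(qr_dec)))[col(q)]
}

#' Initialize parameters of the two-layer GRU classifier
#'
#' Two stacked 64-unit GRU layers (update/reset gating) read the 20
#' timesteps of a window as a sequence of 16-channel observations; the
#' final hidden state of layer 2 feeds a ReLU fully-connected head
#' (hidden -> fc -> 2). Weights are Glorot-uniform, biases zero.
#'
#' @param seed integer seed for the draws.
#' @param n_channels input channels per timestep (16).
#' @param hidden GRU units per layer (64).
#' @param fc width of the fully-connected hidden layer (32).
#' @details Input kernels are Glorot-uniform, recurrent kernels random
#'   orthogonal, biases zero — the conventional recurrent-network
#'   initialization.
#' @return named list of weight matrices and bias vectors.
#' @export
init_gru_params <- function(seed = 1, n_channels = 16, hidden = 64, fc = 32) {
  set.seed(seed)
  layer <- function(d_in) {
    out <- list(Wz = glorot(hidden, d_in), Wr = glorot(hidden, d_in),
                Wc = glorot(hidden, d_in), Uz = orthogonal_init(hidden),
                Ur = orthogonal_init(hidden), Uc = orthogonal_init(hidden),
                bz = numeric(hidden), br = numeric(hidden),
                bc = numeric(hidden))
    out
  }
  l1 <- layer(n_channels)
  l2 <- layer(hidden)
  names(l1) <- paste0(names(l1), "1")
  names(l2) <- paste0(names(l2), "2")
  c(l1, l2,
    list(Wf = glorot(fc, hidden), bf = numeric(fc),
         Wo = glorot(2, fc), bo = numeric(2)))
}

# Flatten a (ch x steps x n) window array into the (ch*steps) x n matrix
# the compiled code consumes (channel fastest within each timestep).
flatten_windows <- function(x) {
  stopifnot(length(dim(x)) == 3)
  matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3])
}

gru_forward <- function(params, xflat, n_channels, n_steps,
                        batch_size = 1024) {
  .cpp_gru_forward(params, xflat, n_channels, n_steps, batch_size)
}
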