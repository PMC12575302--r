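# BiLSTM emission layer: a forward and a backward LSTM pass over the
# context vectors, concatenated per position (h_i in R^{2h}), followed by
# the affine emission map S_i = W h_i + b.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize BiLSTM + emission parameters
#'
#' Gate weights are stacked as 4h-row matrices in gate order
#' (input, forget, output, candidate); the forget-gate bias starts at 1
#' (standard practice for gradient flow).
#'
#' @param d_in Input width (encoder `d_model`).
#' @param hidden Per-direction hidden width `h`.
#' @param k Number of labels (emission rows).
#' @param seed Integer seed.
#' @return List with forward/backward cell parameters (`Wf`, `Uf`, `bf`,
#'   `Wb`, `Ub`, `bb`), emission map (`We`: k x 2h, `be`) and CRF
#'   parameters (`T_mat`, `start`, `stop`).
#' @export
init_bilstm <- function(d_in, hidden, k, seed = 1L) {
  withr::with_seed(seed, {
    sd_w <- 1 / sqrt(d_in); sd_u <- 1 / sqrt(hidden)
    gate_bias <- rep(c(0, 1, 0, 0), each = hidden) # forget bias 1
    list(Wf = rmat(4L * hidden, d_in, sd_w),
         Uf = rmat(4L * hidden, hidden, sd_u),
         bf = gate_bias,
         Wb = rmat(4L * hidden, d_in, sd_w),
         Ub = rmat(4L * hidden, hidden, sd_u),
         bb = gate_bias,
         We = rmat(k, 2L * hidden, 1 / sqrt(2 * hidden)),
         be = rep(0, k),
         T_mat = matrix(0, k, k),
         start = rep(0, k),
         stop = rep(0, k),
         hidden = as.integer(hidden))
  })
}

# One direction LSTM over the rows of X (n x d). Returns hidden states
# (n x h) and, if cache, the per-step gate activations for backprop.
lstm_forward <- function(X, W, U, b, hidden, cache = FALSE) {
  n <- nrow(X)
  H <- matrix(0, n, hidden)
  C <- matrix(0, n, hidden)
  gates <- if (cache) vector("list", n) else NULL
  h_prev <- rep(0, hidden); c_prev <- rep(0, hidden)
  idx_i <- seq_len(hidden); idx_f <- hidden + idx_i
  idx_o <- 2L * hidden + idx_i; idx_g <- 3L * hidden + idx_i
  for (t in seq_len(n)) {
    z <- as.vector(W %*% X[t, ] + U %*% h_prev + b)
    i_g <- sigmoid(z[idx_i]); f_g <- sigmoid(z[idx_f])
    o_g <- sigmoid(z[idx_o]); g_g <- tanh(z[idx_g])
    c_t <- f_g * c_prev + i_g * g_g
    tc <- tanh(c_t)
    h_t <- o_g * tc
    H[t, ] <- h_t; C[t, ] <- c_t
    if (cache) {
      gates[[t]] <- list(i = i_g, f = f_g, o = o_g, g = g_g,
                         c_prev = c_prev, h_prev = h_prev, tc = tc)
    }
    h_prev <- h_t; c_prev <- c_t
  }
  list(H = H, C = C, gates = gates)
}

# Backward pass for one direction. dH: gradient wrt hidden states (n x h).
# Returns parameter gradients and dX (n x d).
lstm_backward <- function(X, W, U, b, hidden, fwd, dH) {
  n <- nrow(X)
  dW <- matrix(0, nrow(W), ncol(W)); dU <- matrix(0, nrow(U), ncol(U))
  db <- rep(0, length(b)); dX <- matrix(0, n, ncol(X))
  dh_next <- rep(0, hidden); dc_next <- rep(0, hidden)
  for (t in rev(seq_len(n))) {
    g <- fwd$gates[[t]]
    dh <- dH[t, ] + dh_next
    do_g <- dh * g$tc
    dc <- dh * g$o * (1 - g$tc^2) + dc_next
    di <- dc * g$g; dg <- dc * g$i; df <- dc * g$c_prev
    dc_next <- dc * g$f
    dz <- c(di * g$i * (1 - g$i), df * g$f * (1 - g$f),
            do_g * g$o * (1 - g$o), dg * (1 - g$g^2))
    dW <- dW + outer(dz, X[t, ])
    dU <- dU + outer(dz, g$h_prev)
    db <- db + dz
    dX[t, ] <- as.vector(crossprod(W, dz))
    dh_next <- as.vector(crossprod(U, dz))
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

#' BiLSTM hidden states
#'
#' Runs a forward LSTM over the input rows and a backward LSTM over the
#' reversed rows, and concatenates the two states at each position:
#' `h_i = concat(h_fwd_i, h_bwd_i)`, width `2h`. Output length equals
#' input length.
#'
#' @param H Context-vector matrix (n x d), e.g. from [encode()] (special
#'   positions removed).
#' @param params Parameters from [init_bilstm()].
#' @return n x 2h matrix of concatenated hidden states.
#' @export
bilstm_hidden <- function(H, params) {
  h <- params$hidden
  fw <- lstm_forward(H, params$Wf, params$Uf, params$bf, h)
  bw <- lstm_forward(H[rev(seq_len(nrow(H))), , drop = FALSE],
                     params$Wb, params$Ub, params$bb, h)
  cbind(fw$H, bw$H[rev(seq_len(nrow(H))), , drop = FALSE])
}

#' Emission scores from hidden states
#'
#' `S_i = W h_i + b` per position: the affine map from the 2h-wide BiLSTM
#' state to one score per label.
#'
#' @param h_seq n x 2h hidden-state matrix.
#' @param W k x 2h weight matrix.
#' @param b Length-k bias.
#' @return n x k emission score matrix.
#' @export
emission_scores <- function(h_seq, W, b) {
  if (ncol(h_seq) != ncol(W)) {
    stop_emrkg("hidden width %d does not match W columns %d",
               ncol(h_seq), ncol(W))
  }
  sweep(h_seq %*% t(W), 2, b, `+`)
}
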