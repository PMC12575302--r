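# Token embedding and stacked multi-head self-attention producing
# contextual vectors H, at configurable toy scale. The encoder contract is
# "token sequence -> context vectors"; the labeler is encoder-agnostic and
# accepts either this transformer or a plain lookup embedder.
#
# Input embedding: E_input = E_t + E_p + E_s (token + position + segment).
# Attention: softmax(Q K^T / sqrt(d_k)) V; heads are concatenated and
# projected by W_o. Residual connections, layer normalization and a
# position-wise feed-forward sublayer are included (pre-LN blocks): the
# bare attention equations alone do not train stably from scratch.

#' Encoder configuration
#'
#' @param vocab Character vector of tokens. The special tokens `[PAD]`,
#'   `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]` are prepended if absent.
#' @param d_model Embedding width; must equal `n_heads * d_k`.
#' @param n_layers Encoder depth (toy default 2; production-scale stacks
#'   run to 24 layers, far beyond desk scale).
#' @param n_heads Attention head count.
#' @param d_k Per-head key/query/value width.
#' @param d_ff Feed-forward inner width.
#' @param max_len Positional table size; must cover the longest wrapped
#'   sequence (tokens + 2 special positions).
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(vocab, d_model = 16L, n_layers = 2L,
                           n_heads = 2L, d_k = d_model %/% n_heads,
                           d_ff = 2L * d_model, max_len = 128L,
                           seed = 1L) {
  specials <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
  vocab <- c(specials, setdiff(vocab, specials))
  if (d_model != n_heads * d_k) {
    stop_emrkg("d_model (%d) must equal n_heads * d_k (%d * %d)",
               d_model, n_heads, d_k)
  }
  structure(list(vocab = vocab, d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_k = as.integer(d_k),
                 d_ff = as.integer(d_ff), max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Initialize toy transformer encoder parameters
#'
#' Seeded Gaussian initialization (scaled by `1/sqrt(d_model)`); layer-norm
#' gains start at 1, biases at 0. The returned model is deterministic in
#' inference mode: the same input always yields bitwise-identical context
#' vectors.
#'
#' @param cfg An [encoder_config()].
#' @return Object of class `toy_encoder` holding embedding tables
#'   (`token_table`, `position_table`, `segment_table`) and per-layer
#'   attention / feed-forward / layer-norm parameters.
#' @export
init_encoder <- function(cfg) {
  stopifnot(inherits(cfg, "encoder_config"))
  d <- cfg$d_model
  withr::with_seed(cfg$seed, {
    sd0 <- 1 / sqrt(d)
    layers <- lapply(seq_len(cfg$n_layers), function(l) {
      list(Wq = rmat(d, d, sd0), Wk = rmat(d, d, sd0),
           Wv = rmat(d, d, sd0), Wo = rmat(d, d, sd0),
           g1 = rep(1, d), b1 = rep(0, d),
           W1 = rmat(d, cfg$d_ff, sd0), bf1 = rep(0, cfg$d_ff),
           W2 = rmat(cfg$d_ff, d, 1 / sqrt(cfg$d_ff)), bf2 = rep(0, d),
           g2 = rep(1, d), b2 = rep(0, d))
    })
    structure(list(config = cfg,
                   token_table = rmat(length(cfg$vocab), d, sd0),
                   position_table = rmat(cfg$max_len, d, sd0),
                   segment_table = rmat(1L, d, sd0),
                   layers = layers),
              class = "toy_encoder")
  })
}

token_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- match("[UNK]", vocab)
  ids
}

#' Sum token, position and segment embeddings
#'
#' Computes the input embedding `E_input = E_t + E_p + E_s` for a wrapped
#' token sequence: position `i`'s vector is the elementwise sum of its
#' token vector, the `i`-th position vector, and the (single-segment)
#' segment vector. Inputs are single sentences, so the segment index is
#' constant.
#'
#' @param tokens Character vector already wrapped with `[CLS]` / `[SEP]`;
#'   out-of-vocabulary tokens map to `[UNK]`.
#' @param tables A `toy_encoder` (or any list with `token_table`,
#'   `position_table`, `segment_table` and a `config$vocab`).
#' @return Numeric matrix, one row per token, `d_model` columns.
#' @export
embed_input <- function(tokens, tables) {
  vocab <- tables$config$vocab
  n <- length(tokens)
  if (n > nrow(tables$position_table)) {
    stop_emrkg("sequence length %d exceeds max_len %d", n,
               nrow(tables$position_table))
  }
  ids <- token_ids(tokens, vocab)
  tables$token_table[ids, , drop = FALSE] +
    tables$position_table[seq_len(n), , drop = FALSE] +
    matrix(tables$segment_table[1L, ], n, ncol(tables$token_table),
           byrow = TRUE)
}

row_softmax <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V`. Each output row is
#' a convex combination of the rows of `V`: the attention weight rows are
#' nonnegative and sum to 1, and adding a constant to every logit in a row
#' leaves the output unchanged (softmax shift invariance).
#'
#' @param Q,K,V Conformable matrices (`Q`: n x d_k, `K`: m x d_k, `V`:
#'   m x d_v).
#' @param d_k Scaling dimension, default `ncol(K)`; must be positive.
#' @return n x d_v matrix with the weight matrix in `attr(, "weights")`.
#' @export
attention <- function(Q, K, V, d_k = ncol(K)) {
  if (d_k <= 0) stop_emrkg("d_k must be positive")
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    stop_emrkg("non-conformable Q/K/V")
  }
  W <- row_softmax(Q %*% t(K) / sqrt(d_k))
  out <- W %*% V
  attr(out, "weights") <- W
  out
}

#' Multi-head attention
#'
#' Projects `Q`, `K`, `V` through each head, concatenates the per-head
#' attention outputs, and applies the output projection:
#' `Concat(head_1, ..., head_n) W_o`.
#'
#' @param Q,K,V Input matrices.
#' @param heads List of heads, each a list with projection matrices `Wq`,
#'   `Wk`, `Wv`.
#' @param W_o Output projection; its row count must equal the concatenated
#'   head width.
#' @return Matrix of `nrow(Q)` rows and `ncol(W_o)` columns.
#' @export
multi_head <- function(Q, K, V, heads, W_o) {
  outs <- lapply(heads, function(h) {
    attention(Q %*% h$Wq, K %*% h$Wk, V %*% h$Wv)
  })
  cat_out <- do.call(cbind, outs)
  if (ncol(cat_out) != nrow(W_o)) {
    stop_emrkg("concatenated head width %d does not match W_o rows %d",
               ncol(cat_out), nrow(W_o))
  }
  cat_out %*% W_o
}

layer_norm <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  Xhat <- (X - mu) / sqrt(v + eps)
  sweep(sweep(Xhat, 2, g, `*`), 2, b, `+`)
}

# One pre-LN encoder block forward. Returns output plus a cache for
# backprop (see fit.R).
encoder_block <- function(X, lp, n_heads, d_k, cache = FALSE) {
  d <- ncol(X)
  A_in <- layer_norm(X, lp$g1, lp$b1)
  Q <- A_in %*% lp$Wq; K <- A_in %*% lp$Wk; V <- A_in %*% lp$Wv
  heads <- vector("list", n_heads)
  P <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * d_k + 1L):(h * d_k)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(d_k)
    P[[h]] <- row_softmax(S)
    heads[[h]] <- P[[h]] %*% V[, cols, drop = FALSE]
  }
  O <- do.call(cbind, heads)
  X1 <- X + O %*% lp$Wo
  F_in <- layer_norm(X1, lp$g2, lp$b2)
  Hpre <- F_in %*% lp$W1
  Hpre <- sweep(Hpre, 2, lp$bf1, `+`)
  Hact <- pmax(Hpre, 0)
  FF <- sweep(Hact %*% lp$W2, 2, lp$bf2, `+`)
  X2 <- X1 + FF
  if (!cache) return(X2)
  list(out = X2, X = X, A_in = A_in, Q = Q, K = K, V = V, P = P, O = O,
       X1 = X1, F_in = F_in, Hpre = Hpre, Hact = Hact)
}

#' Encode a token sequence into context vectors
#'
#' Wraps the tokens with `[CLS]` / `[SEP]`, embeds them ([embed_input()]),
#' and passes the result through the configured stack of encoder blocks.
#' With `n_layers = 0` the output equals the input embedding. Output
#' length is `length(tokens) + 2` (the two special positions), width
#' `d_model`.
#'
#' @param tokens Character vector of unwrapped tokens.
#' @param model A `toy_encoder` from [init_encoder()].
#' @return Context-vector matrix `H` (rows: `[CLS]`, tokens, `[SEP]`).
#' @export
encode <- function(tokens, model) {
  stopifnot(inherits(model, "toy_encoder"))
  wrapped <- c("[CLS]", tokens, "[SEP]")
  X <- embed_input(wrapped, model)
  for (lp in model$layers) {
    X <- encoder_block(X, lp, model$config$n_heads, model$config$d_k)
  }
  rownames(X) <- NULL
  X
}

#' Plain lookup embedder
#'
#' The minimal implementation of the encoder contract: context vector =
#' token embedding + position embedding (no attention). Useful for fast
#' tests and as a trainable baseline encoder.
#'
#' @inheritParams init_encoder
#' @return Object of classes `lookup_encoder`; [encode_lookup()] maps
#'   tokens to vectors.
#' @export
init_lookup_encoder <- function(cfg) {
  stopifnot(inherits(cfg, "encoder_config"))
  withr::with_seed(cfg$seed, {
    structure(list(config = cfg,
                   token_table = rmat(length(cfg$vocab), cfg$d_model,
                                      1 / sqrt(cfg$d_model)),
                   position_table = rmat(cfg$max_len, cfg$d_model,
                                         1 / sqrt(cfg$d_model)),
                   segment_table = matrix(0, 1L, cfg$d_model)),
              class = "lookup_encoder")
  })
}

#' @rdname init_lookup_encoder
#' @param tokens Unwrapped token vector.
#' @param model A `lookup_encoder`.
#' @export
encode_lookup <- function(tokens, model) {
  embed_input(c("[CLS]", tokens, "[SEP]"), model)
}
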