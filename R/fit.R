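# Joint training of the toy encoder + BiLSTM + CRF stack by gradient
# descent on the mean CRF negative log-likelihood, with handwritten
# reverse-mode gradients (no autodiff dependency). Special positions
# ([CLS]/[SEP]) carry no labels: they are excluded from the emission
# matrix and the loss.

ln_backward <- function(dY, X, g, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  sdv <- sqrt(v + eps)
  Xhat <- (X - mu) / sdv
  dXhat <- sweep(dY, 2, g, `*`)
  dX <- (dXhat - rowMeans(dXhat) - Xhat * rowMeans(dXhat * Xhat)) / sdv
  list(dX = dX, dg = colSums(dY * Xhat), db = colSums(dY))
}

encoder_block_backward <- function(dX2, cache, lp, n_heads, d_k) {
  # FFN sublayer (pre-LN): X2 = X1 + FF(LN(X1))
  dX1 <- dX2
  dFF <- dX2
  dHact <- dFF %*% t(lp$W2)
  dW2 <- crossprod(cache$Hact, dFF)
  dbf2 <- colSums(dFF)
  dHpre <- dHact * (cache$Hpre > 0)
  dW1 <- crossprod(cache$F_in, dHpre)
  dbf1 <- colSums(dHpre)
  dF_in <- dHpre %*% t(lp$W1)
  ln2 <- ln_backward(dF_in, cache$X1, lp$g2)
  dX1 <- dX1 + ln2$dX
  # attention sublayer: X1 = X + MHA(LN(X)) Wo
  dM <- dX1
  dX <- dX1
  dO <- dM %*% t(lp$Wo)
  dWo <- crossprod(cache$O, dM)
  d <- ncol(cache$X)
  dQ <- matrix(0, nrow(cache$X), d)
  dK <- matrix(0, nrow(cache$X), d)
  dV <- matrix(0, nrow(cache$X), d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * d_k + 1L):(h * d_k)
    P <- cache$P[[h]]
    Vh <- cache$V[, cols, drop = FALSE]
    dOh <- dO[, cols, drop = FALSE]
    dP <- dOh %*% t(Vh)
    dV[, cols] <- crossprod(P, dOh)
    dS <- P * (dP - rowSums(dP * P))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(d_k)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(d_k)
  }
  dA_in <- dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
  dWq <- crossprod(cache$A_in, dQ)
  dWk <- crossprod(cache$A_in, dK)
  dWv <- crossprod(cache$A_in, dV)
  ln1 <- ln_backward(dA_in, cache$X, lp$g1)
  dX <- dX + ln1$dX
  list(dX = dX,
       grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo,
                    g1 = ln1$dg, b1 = ln1$db,
                    W1 = dW1, bf1 = dbf1, W2 = dW2, bf2 = dbf2,
                    g2 = ln2$dg, b2 = ln2$db))
}

# forward pass for one sequence with caches; y_idx NULL for inference
labeler_forward <- function(model, tokens, y_idx = NULL, cache = FALSE) {
  wrapped <- c("[CLS]", tokens, "[SEP]")
  ids <- token_ids(wrapped, model$encoder$config$vocab)
  X <- embed_input(wrapped, model$encoder)
  caches <- NULL
  if (model$enc_type == "transformer") {
    caches <- vector("list", length(model$encoder$layers))
    for (l in seq_along(model$encoder$layers)) {
      res <- encoder_block(X, model$encoder$layers[[l]],
                           model$encoder$config$n_heads,
                           model$encoder$config$d_k, cache = cache)
      if (cache) { caches[[l]] <- res; X <- res$out } else X <- res
    }
  }
  n <- length(tokens)
  Henc <- X[1L + seq_len(n), , drop = FALSE]
  p <- model$params
  fw <- lstm_forward(Henc, p$Wf, p$Uf, p$bf, p$hidden, cache = cache)
  rev_idx <- rev(seq_len(n))
  bw <- lstm_forward(Henc[rev_idx, , drop = FALSE], p$Wb, p$Ub, p$bb,
                     p$hidden, cache = cache)
  G <- cbind(fw$H, bw$H[rev_idx, , drop = FALSE])
  S <- emission_scores(G, p$We, p$be)
  out <- list(S = S, G = G, Henc = Henc, ids = ids, fw = fw, bw = bw,
              caches = caches, n = n)
  if (!is.null(y_idx)) {
    out$loss <- nll_loss(S, p$T_mat, y_idx, model$scheme, p$start, p$stop)
  }
  out
}

# gradients for one sequence; returns named flat list mirroring the
# parameter layout plus embedding-table gradients
labeler_backward <- function(model, fwdc, y_idx) {
  p <- model$params
  n <- fwdc$n
  k <- ncol(fwdc$S)
  marg <- crf_marginals(fwdc$S, p$T_mat, model$scheme, p$start, p$stop)
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), y_idx)] <- 1
  dS <- marg$unary - onehot
  obs_T <- matrix(0, k, k)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      obs_T[y_idx[i], y_idx[i + 1]] <- obs_T[y_idx[i], y_idx[i + 1]] + 1
    }
  }
  g <- list(T_mat = marg$pair - obs_T,
            start = unname(marg$p_start) - onehot[1, ],
            stop = unname(marg$p_stop) - onehot[n, ],
            We = crossprod(dS, fwdc$G),
            be = colSums(dS))
  dG <- dS %*% p$We
  h <- p$hidden
  rev_idx <- rev(seq_len(n))
  bwd_f <- lstm_backward(fwdc$Henc, p$Wf, p$Uf, p$bf, h, fwdc$fw,
                         dG[, seq_len(h), drop = FALSE])
  bwd_b <- lstm_backward(fwdc$Henc[rev_idx, , drop = FALSE],
                         p$Wb, p$Ub, p$bb, h, fwdc$bw,
                         dG[rev_idx, h + seq_len(h), drop = FALSE])
  g$Wf <- bwd_f$dW; g$Uf <- bwd_f$dU; g$bf <- bwd_f$db
  g$Wb <- bwd_b$dW; g$Ub <- bwd_b$dU; g$bb <- bwd_b$db
  dHenc <- bwd_f$dX + bwd_b$dX[rev_idx, , drop = FALSE]
  dX <- matrix(0, n + 2L, ncol(dHenc))
  dX[1L + seq_len(n), ] <- dHenc
  enc_grads <- list()
  if (model$enc_type == "transformer") {
    for (l in rev(seq_along(model$encoder$layers))) {
      bb <- encoder_block_backward(dX, fwdc$caches[[l]],
                                   model$encoder$layers[[l]],
                                   model$encoder$config$n_heads,
                                   model$encoder$config$d_k)
      dX <- bb$dX
      enc_grads[[paste0("layer", l)]] <- bb$grads
    }
  }
  # embedding tables: scatter-add over token ids / positions
  dtok <- matrix(0, nrow(model$encoder$token_table),
                 ncol(model$encoder$token_table))
  for (t in seq_along(fwdc$ids)) {
    dtok[fwdc$ids[t], ] <- dtok[fwdc$ids[t], ] + dX[t, ]
  }
  dpos <- matrix(0, nrow(model$encoder$position_table),
                 ncol(model$encoder$position_table))
  dpos[seq_len(n + 2L), ] <- dX
  g$token_table <- dtok
  g$position_table <- dpos
  g$segment_table <- matrix(colSums(dX), 1L)
  g$enc_layers <- enc_grads
  g
}

# --- Adam over the nested parameter structure ---------------------------

flatten_params <- function(model) {
  out <- model$params[c("Wf", "Uf", "bf", "Wb", "Ub", "bb", "We", "be",
                        "T_mat", "start", "stop")]
  out$token_table <- model$encoder$token_table
  out$position_table <- model$encoder$position_table
  out$segment_table <- model$encoder$segment_table
  if (model$enc_type == "transformer") {
    for (l in seq_along(model$encoder$layers)) {
      for (nm in names(model$encoder$layers[[l]])) {
        out[[sprintf("layer%d.%s", l, nm)]] <- model$encoder$layers[[l]][[nm]]
      }
    }
  }
  out
}

unflatten_params <- function(model, flat) {
  for (nm in c("Wf", "Uf", "bf", "Wb", "Ub", "bb", "We", "be",
               "T_mat", "start", "stop")) {
    model$params[[nm]] <- flat[[nm]]
  }
  model$encoder$token_table <- flat$token_table
  model$encoder$position_table <- flat$position_table
  model$encoder$segment_table <- flat$segment_table
  if (model$enc_type == "transformer") {
    for (l in seq_along(model$encoder$layers)) {
      for (nm in names(model$encoder$layers[[l]])) {
        model$encoder$layers[[l]][[nm]] <- flat[[sprintf("layer%d.%s", l, nm)]]
      }
    }
  }
  model
}

flatten_grads <- function(g, model) {
  out <- g[c("Wf", "Uf", "bf", "Wb", "Ub", "bb", "We", "be",
             "T_mat", "start", "stop",
             "token_table", "position_table", "segment_table")]
  if (model$enc_type == "transformer") {
    for (l in seq_along(model$encoder$layers)) {
      lg <- g$enc_layers[[paste0("layer", l)]]
      for (nm in names(lg)) out[[sprintf("layer%d.%s", l, nm)]] <- lg[[nm]]
    }
  }
  out
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

adam_step <- function(flat, grads, state, lr, clip = 5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  flat
}

# --- public training / prediction API -----------------------------------

labels_to_idx <- function(labels, scheme) {
  idx <- match(labels, scheme$labels)
  if (anyNA(idx)) {
    stop_emrkg("label(s) outside the scheme: %s",
               paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Assemble an untrained labeler model
#'
#' @param vocab Token vocabulary (specials are added automatically).
#' @param entity_types Entity types defining the BIO label scheme.
#' @param encoder `"transformer"` (toy self-attention stack, default) or
#'   `"lookup"` (plain trainable embedding).
#' @param d_model,n_layers,n_heads,hidden Architecture sizes (toy-scale
#'   defaults: d = 16, 2 layers, 2 heads, h = 16).
#' @param max_len Positional table size.
#' @param constrain BIO transition constraints in the CRF (default on).
#' @param seed Integer seed for initialization.
#' @return Object of class `labeler_model`.
#' @export
labeler_model <- function(vocab, entity_types,
                          encoder = c("transformer", "lookup"),
                          d_model = 16L, n_layers = 2L, n_heads = 2L,
                          hidden = 16L, max_len = 128L, constrain = TRUE,
                          seed = 1L) {
  enc_type <- match.arg(encoder)
  cfg <- encoder_config(vocab, d_model = d_model, n_layers = n_layers,
                        n_heads = n_heads, max_len = max_len, seed = seed)
  enc <- if (enc_type == "transformer") init_encoder(cfg) else
    init_lookup_encoder(cfg)
  scheme <- bio_label_scheme(entity_types, constrain = constrain)
  params <- init_bilstm(d_model, hidden, length(scheme$labels),
                        seed = seed + 1L)
  structure(list(encoder = enc, enc_type = enc_type, scheme = scheme,
                 params = params, entity_types = entity_types,
                 history = numeric()),
            class = "labeler_model")
}

#' Train the BiLSTM-CRF labeler
#'
#' Minimizes the mean per-sequence CRF negative log-likelihood over the
#' training corpus by mini-batch Adam, backpropagating through the
#' emission map, both LSTM directions and (for the transformer encoder)
#' the full attention stack and embedding tables. Deterministic given
#' `seed`. Training diverging to a non-finite loss is an error.
#'
#' @param train_seqs List of BIO-valid [tag_sequence()] objects; must be
#'   non-empty.
#' @param entity_types Entity types of the label scheme; default inferred
#'   from the training labels.
#' @param encoder,d_model,n_layers,n_heads,hidden,constrain Passed to
#'   [labeler_model()].
#' @param epochs,lr,batch_size,clip Optimization settings. These are
#'   package defaults documented here, not values taken from any reference
#'   training run.
#' @param derm Optional [derm_config()]; when supplied the training set is
#'   re-augmented at every epoch (`derm_mode = "epoch"`) or once up front
#'   (`"once"`).
#' @param derm_mode See above.
#' @param seed Integer seed governing initialization, shuffling and DERM.
#' @param verbose Print per-epoch mean loss.
#' @return A trained `labeler_model`; `$history` holds the per-epoch mean
#'   training loss.
#' @export
fit_labeler <- function(train_seqs, entity_types = NULL,
                        encoder = c("transformer", "lookup"),
                        d_model = 16L, n_layers = 2L, n_heads = 2L,
                        hidden = 16L, constrain = TRUE,
                        epochs = 6L, lr = 0.01, batch_size = 8L, clip = 5,
                        derm = NULL, derm_mode = c("epoch", "once"),
                        seed = 42L, verbose = FALSE) {
  if (!length(train_seqs)) stop_emrkg("empty training corpus")
  derm_mode <- match.arg(derm_mode)
  if (is.null(entity_types)) {
    labs <- unique(unlist(lapply(train_seqs, `[[`, "labels")))
    entity_types <- sort(unique(sub("^[BI]-", "", labs[labs != "O"])))
  }
  vocab <- sort(unique(unlist(lapply(train_seqs, `[[`, "tokens"))))
  if (!is.null(derm)) {
    vocab <- sort(unique(c(vocab, derm$mask_token,
                           unlist(strsplit(unlist(derm$dictionaries), "")))))
  }
  max_len <- max(vapply(train_seqs, function(s) length(s$tokens),
                        integer(1))) + 12L
  model <- labeler_model(vocab, entity_types, encoder, d_model, n_layers,
                         n_heads, hidden, max_len, constrain, seed)
  flat <- flatten_params(model)
  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()
  withr::with_seed(seed, {
    seqs_fixed <- if (!is.null(derm) && derm_mode == "once") {
      augment_corpus(train_seqs, derm, pass = 1L)
    } else train_seqs
    for (ep in seq_len(epochs)) {
      seqs_ep <- if (!is.null(derm) && derm_mode == "epoch") {
        augment_corpus(train_seqs, derm, pass = ep)
      } else seqs_fixed
      ord <- sample.int(length(seqs_ep))
      ep_loss <- 0
      acc <- NULL; in_batch <- 0L
      for (si in ord) {
        s <- seqs_ep[[si]]
        if (!length(s$tokens)) next
        y <- labels_to_idx(s$labels, model$scheme)
        fwdc <- labeler_forward(model, s$tokens, y, cache = TRUE)
        if (!is.finite(fwdc$loss)) {
          stop_emrkg("training diverged (non-finite loss at epoch %d)", ep)
        }
        ep_loss <- ep_loss + fwdc$loss
        g <- flatten_grads(labeler_backward(model, fwdc, y), model)
        acc <- add_grads(acc, g)
        in_batch <- in_batch + 1L
        if (in_batch == batch_size) {
          acc <- lapply(acc, `/`, in_batch)
          flat <- adam_step(flat, acc, state, lr, clip)
          model <- unflatten_params(model, flat)
          acc <- NULL; in_batch <- 0L
        }
      }
      if (in_batch > 0L) {
        acc <- lapply(acc, `/`, in_batch)
        flat <- adam_step(flat, acc, state, lr, clip)
        model <- unflatten_params(model, flat)
      }
      model$history <- c(model$history, ep_loss / length(seqs_ep))
      if (verbose) {
        message(sprintf("epoch %d: mean NLL %.4f", ep,
                        ep_loss / length(seqs_ep)))
      }
    }
  })
  model
}

#' Mean labeler loss on a corpus
#'
#' Mean per-sequence CRF negative log-likelihood without any parameter
#' update (e.g. to check descent or monitor a dev set).
#'
#' @param model A `labeler_model`.
#' @param seqs List of gold [tag_sequence()] objects.
#' @return Scalar mean loss.
#' @export
labeler_loss <- function(model, seqs) {
  tot <- 0
  for (s in seqs) {
    y <- labels_to_idx(s$labels, model$scheme)
    tot <- tot + labeler_forward(model, s$tokens, y)$loss
  }
  tot / length(seqs)
}

#' Predict BIO labels for token sequences
#'
#' Runs the encoder + BiLSTM forward pass and decodes each sequence with
#' constrained Viterbi ([viterbi_decode()]), so the output labels are
#' always BIO-valid when the model was built with constraints.
#'
#' @param model A trained `labeler_model`.
#' @param seqs List of [tag_sequence()] objects (labels, if present, are
#'   ignored).
#' @return List of [tag_sequence()] objects with predicted labels and the
#'   input token offsets.
#' @export
predict_labeler <- function(model, seqs) {
  lapply(seqs, function(s) {
    if (!length(s$tokens)) return(s)
    fwdc <- labeler_forward(model, s$tokens)
    dec <- viterbi_decode(fwdc$S, model$params$T_mat, model$scheme,
                          model$params$start, model$params$stop)
    tag_sequence(s$tokens, model$scheme$labels[dec$path], s$char_offsets,
                 validate = FALSE)
  })
}

#' Exact-match evaluation of a labeler on gold sequences
#'
#' Decodes the sequences, converts predicted and gold labels to spans, and
#' micro-averages exact-match precision/recall/F1 over the corpus.
#'
#' @param model A trained `labeler_model`.
#' @param seqs Gold [tag_sequence()] objects.
#' @return List with `counts` (a `match_counts`) and `metrics`
#'   (percent P/R/F1 from [prf()]).
#' @export
evaluate_labeler <- function(model, seqs) {
  preds <- predict_labeler(model, seqs)
  tp <- fp <- fn <- 0L
  for (i in seq_along(seqs)) {
    g <- bio_to_spans(seqs[[i]], strict = FALSE)
    p <- bio_to_spans(preds[[i]], strict = FALSE)
    m <- match_entities(p, g)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  counts <- match_counts(tp, fp, fn)
  list(counts = counts, metrics = prf(counts))
}
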