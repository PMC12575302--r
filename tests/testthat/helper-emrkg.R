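# Shared fixtures and independent oracles, built in code at test time.

# small annotated corpus with gold spans
small_corpus <- function(n_docs = 20, mentions = 2, seed = 101) {
  cfg <- generator_config(n_docs = n_docs, mentions_per_doc = mentions,
                          seed = seed)
  list(cfg = cfg, dicts = generate_dictionaries(cfg),
       docs = generate_corpus(cfg))
}

corpus_seqs <- function(docs) {
  unlist(lapply(docs, spans_to_bio), recursive = FALSE)
}

# enumeration oracle: score of every label sequence (k^n rows)
enum_all_scores <- function(S, T_mat, start = NULL, stop = NULL) {
  n <- nrow(S); k <- ncol(S)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  scores <- apply(grid, 1, function(y) {
    sequence_score(S, T_mat, as.integer(y), start, stop)
  })
  list(paths = grid, scores = scores)
}

# enumeration restricted to BIO-valid sequences under a scheme
enum_allowed_scores <- function(S, T_mat, scheme, start = NULL,
                                stop = NULL) {
  e <- enum_all_scores(S, T_mat, start, stop)
  ok <- apply(e$paths, 1, function(y) {
    y <- as.integer(y)
    if (!scheme$starts[y[1]]) return(FALSE)
    if (length(y) > 1) {
      for (i in seq_len(length(y) - 1)) {
        if (!scheme$transitions[y[i], y[i + 1]]) return(FALSE)
      }
    }
    scheme$ends[y[length(y)]]
  })
  list(paths = e$paths[ok, , drop = FALSE], scores = e$scores[ok])
}

# independent multi-hop oracle: adjacency-matrix propagation per relation
multihop_oracle <- function(store, start_type, start_name, path) {
  keys <- paste(store$entities$entity_type, store$entities$name, sep = "/")
  v <- as.numeric(keys == paste(start_type, start_name, sep = "/"))
  for (rel in path) {
    tr <- store$triples[store$triples$relation == rel, , drop = FALSE]
    A <- matrix(0, length(keys), length(keys))
    if (nrow(tr)) {
      si <- match(paste(tr$subject_type, tr$subject, sep = "/"), keys)
      oi <- match(paste(tr$object_type, tr$object, sep = "/"), keys)
      A[cbind(si, oi)] <- 1
    }
    v <- as.numeric(crossprod(A, v) > 0)
  }
  sort(keys[v > 0])
}
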