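test_that("sequence_score implements the emission + transition sum", {
  S <- rbind(c(1, 0), c(0, 2), c(1, 1))
  T_mat <- rbind(c(0, 1), c(1, 0))
  expect_identical(sequence_score(S, T_mat, c(1, 2, 1)), 6)
  expect_identical(sequence_score(matrix(0, 4, 3), matrix(0, 3, 3),
                                  c(1, 3, 2, 2)), 0)
  # n = 1: no transition term
  expect_identical(sequence_score(matrix(c(2, 5), 1, 2), T_mat, 2), 5)
  # boundary scores are additive when supplied
  expect_identical(sequence_score(S, T_mat, c(1, 2, 1),
                                  start = c(10, 0), stop = c(0.5, 0)),
                   16.5)
  expect_error(sequence_score(S, T_mat, c(1, 5, 1)), "indices")
})

test_that("log_partition matches enumeration and closed forms", {
  # n = 1: log-sum-exp of the single emission row
  S1 <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(log_partition(S1, matrix(0, 3, 3)),
               log(sum(exp(c(1, 2, 3)))), tolerance = 1e-12)
  # uniform case: log(k^n) = n log k
  expect_equal(log_partition(matrix(0, 4, 3), matrix(0, 3, 3)),
               4 * log(3), tolerance = 1e-12)
  # random integer instance vs brute-force enumeration over 27 sequences
  set.seed(7)
  S <- matrix(sample(-3:3, 9, TRUE), 3, 3)
  T_mat <- matrix(sample(-2:2, 9, TRUE), 3, 3)
  e <- enum_all_scores(S, T_mat)
  expect_equal(log_partition(S, T_mat), log(sum(exp(e$scores))),
               tolerance = 1e-9)
})

test_that("nll_loss is a proper negative log-likelihood", {
  # k = 1: a single possible sequence, loss exactly 0
  expect_equal(nll_loss(matrix(c(3, 1), 2, 1), matrix(2, 1, 1), c(1, 1)),
               0, tolerance = 1e-12)
  set.seed(8)
  S <- matrix(rnorm(6), 3, 2)
  T_mat <- matrix(rnorm(4), 2, 2)
  e <- enum_all_scores(S, T_mat)
  # probabilities over all label sequences sum to 1
  probs <- exp(-vapply(seq_len(nrow(e$paths)), function(i) {
    nll_loss(S, T_mat, as.integer(e$paths[i, ]))
  }, numeric(1)))
  expect_equal(sum(probs), 1, tolerance = 1e-9)
  expect_true(all(probs >= 0))
  # raising the gold emission strictly decreases the loss
  y <- c(1, 2, 1)
  l0 <- nll_loss(S, T_mat, y)
  expect_gte(l0, 0)
  S2 <- S; S2[2, 2] <- S2[2, 2] + 0.5
  expect_lt(nll_loss(S2, T_mat, y), l0)
})

test_that("viterbi matches exhaustive argmax on random instances", {
  set.seed(9)
  for (rep in 1:120) {
    n <- sample(1:4, 1); k <- sample(2:3, 1)
    S <- matrix(rnorm(n * k), n, k)
    T_mat <- matrix(rnorm(k * k), k, k)
    use_bound <- rep %% 2 == 0
    st <- if (use_bound) rnorm(k) else NULL
    en <- if (use_bound) rnorm(k) else NULL
    e <- enum_all_scores(S, T_mat, st, en)
    dec <- viterbi_decode(S, T_mat, start = st, stop = en)
    best <- which.max(e$scores)
    expect_equal(dec$score, e$scores[best], tolerance = 1e-9)
    expect_identical(dec$path, as.integer(e$paths[best, ]))
    expect_equal(log_partition(S, T_mat, start = st, stop = en),
                 log(sum(exp(e$scores - max(e$scores)))) + max(e$scores),
                 tolerance = 1e-9)
  }
  # n = 1 reduces to the row argmax
  expect_identical(viterbi_decode(matrix(c(1, 9, 2), 1, 3),
                                  matrix(0, 3, 3))$path, 2L)
  # exact ties break toward the lowest label index at every step
  tie <- viterbi_decode(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_identical(tie$path, c(1L, 1L, 1L))
})

test_that("constrained decoding and partition respect the BIO mask", {
  scheme <- bio_label_scheme("disease")
  k <- length(scheme$labels)
  expect_false(scheme$transitions["O", "I-disease"])
  expect_false(scheme$starts["I-disease"])
  set.seed(10)
  for (rep in 1:40) {
    n <- sample(2:4, 1)
    S <- matrix(rnorm(n * k, sd = 3), n, k)
    T_mat <- matrix(rnorm(k * k), k, k)
    dec <- viterbi_decode(S, T_mat, scheme)
    expect_true(is_bio_valid(scheme$labels[dec$path]))
    e <- enum_allowed_scores(S, T_mat, scheme)
    best <- which.max(e$scores)
    expect_equal(dec$score, e$scores[best], tolerance = 1e-9)
    expect_equal(log_partition(S, T_mat, scheme),
                 log(sum(exp(e$scores - max(e$scores)))) + max(e$scores),
                 tolerance = 1e-9)
  }
  # every label reachable; unconstrained scheme allows everything
  free <- bio_label_scheme("disease", constrain = FALSE)
  expect_true(all(free$transitions))
})

test_that("forward-backward marginals match enumeration", {
  set.seed(11)
  S <- matrix(rnorm(8), 4, 2)
  T_mat <- matrix(rnorm(4), 2, 2)
  e <- enum_all_scores(S, T_mat)
  w <- exp(e$scores - max(e$scores)); w <- w / sum(w)
  marg <- emrkg:::crf_marginals(S, T_mat)
  for (i in 1:4) {
    for (j in 1:2) {
      expect_equal(marg$unary[i, j], sum(w[e$paths[, i] == j]),
                   tolerance = 1e-9)
    }
  }
  # expected transition counts
  for (a in 1:2) for (b in 1:2) {
    cnt <- vapply(seq_len(nrow(e$paths)), function(r) {
      y <- e$paths[r, ]
      sum(y[-4] == a & y[-1] == b)
    }, numeric(1))
    expect_equal(marg$pair[a, b], sum(w * cnt), tolerance = 1e-9)
  }
})
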