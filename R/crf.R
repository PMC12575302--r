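# Linear-chain CRF over BIO label sequences: sequence scoring, a log-space
# forward algorithm for the partition function, forward-backward marginals
# for training, and constrained Viterbi decoding.
#
# Score(X, y) = sum_i S[i, y_i] + sum_i T[y_i, y_{i+1}] with optional
# start/stop boundary scores; p(y|X) = exp(Score) / sum_y' exp(Score').

#' BIO label scheme with transition constraints
#'
#' Builds the ordered label set `O, B-t1, I-t1, B-t2, ...` for the given
#' entity types together with the boolean transition mask enforcing BIO
#' validity: `I-x` may only follow `B-x` or `I-x` (so `O -> I-x` and
#' `B-y -> I-x` are disallowed), and no sequence may start with `I-x`.
#'
#' @param entity_types Character vector of entity types.
#' @param constrain Apply the BIO mask (default `TRUE`); with `FALSE` all
#'   transitions, starts and ends are allowed.
#' @return Object of class `label_scheme`: list with `labels`,
#'   `transitions` (k x k logical), `starts`, `ends` (logical k-vectors).
#' @export
bio_label_scheme <- function(entity_types, constrain = TRUE) {
  labels <- c("O", as.vector(rbind(paste0("B-", entity_types),
                                   paste0("I-", entity_types))))
  k <- length(labels)
  trans <- matrix(TRUE, k, k, dimnames = list(labels, labels))
  starts <- rep(TRUE, k); names(starts) <- labels
  if (constrain) {
    for (j in seq_len(k)) {
      if (startsWith(labels[j], "I-")) {
        tp <- sub("^I-", "", labels[j])
        ok_prev <- labels %in% paste0(c("B-", "I-"), tp)
        trans[!ok_prev, j] <- FALSE
        starts[j] <- FALSE
      }
    }
  }
  structure(list(labels = labels,
                 transitions = trans,
                 starts = starts,
                 ends = stats::setNames(rep(TRUE, k), labels)),
            class = "label_scheme")
}

# additive -Inf masks derived from the scheme (NULL scheme = unmasked)
scheme_masks <- function(scheme, k) {
  if (is.null(scheme)) {
    return(list(T = matrix(0, k, k), start = rep(0, k), end = rep(0, k)))
  }
  stopifnot(length(scheme$labels) == k)
  list(T = ifelse(scheme$transitions, 0, -Inf),
       start = ifelse(scheme$starts, 0, -Inf),
       end = ifelse(scheme$ends, 0, -Inf))
}

#' Score one label sequence
#'
#' `Score(X, y) = sum_{i=1..n} S[i, y_i] + sum_{i=1..n-1} T[y_i, y_{i+1}]`,
#' plus optional boundary scores `start[y_1] + stop[y_n]`.
#'
#' @param S n x k emission score matrix.
#' @param T_mat k x k transition score matrix.
#' @param y Integer label indices (length n, values in `1..k`).
#' @param start,stop Optional length-k boundary score vectors (default
#'   zero contribution, i.e. the bare two-term score).
#' @return Scalar score.
#' @examples
#' S <- rbind(c(1, 0), c(0, 2), c(1, 1))
#' T_mat <- rbind(c(0, 1), c(1, 0))
#' sequence_score(S, T_mat, c(1, 2, 1)) # 6
#' @export
sequence_score <- function(S, T_mat, y, start = NULL, stop = NULL) {
  n <- nrow(S); k <- ncol(S)
  y <- as.integer(y)
  if (length(y) != n || any(y < 1 | y > k)) {
    stop_emrkg("y must hold %d label indices in 1..%d", n, k)
  }
  sc <- sum(S[cbind(seq_len(n), y)])
  if (n > 1) sc <- sc + sum(T_mat[cbind(y[-n], y[-1])])
  if (!is.null(start)) sc <- sc + start[y[1]]
  if (!is.null(stop)) sc <- sc + stop[y[n]]
  sc
}

#' Log partition function (forward algorithm)
#'
#' Computes `log sum_y' exp(Score(X, y'))` over all label sequences allowed
#' by `scheme`, in log space with log-sum-exp stabilization. Disallowed
#' transitions contribute zero mass (additive `-Inf` masking).
#'
#' @inheritParams sequence_score
#' @param scheme Optional [bio_label_scheme()]; `NULL` sums over all
#'   `k^n` sequences.
#' @return Scalar log partition value.
#' @export
log_partition <- function(S, T_mat, scheme = NULL, start = NULL,
                          stop = NULL) {
  n <- nrow(S); k <- ncol(S)
  masks <- scheme_masks(scheme, k)
  Tm <- T_mat + masks$T
  alpha <- S[1, ] + masks$start + (if (is.null(start)) 0 else start)
  if (n > 1) {
    for (i in 2:n) {
      alpha <- vapply(seq_len(k), function(j) {
        logsumexp(alpha + Tm[, j])
      }, numeric(1)) + S[i, ]
    }
  }
  z <- logsumexp(alpha + masks$end + (if (is.null(stop)) 0 else stop))
  if (!is.finite(z)) stop_emrkg("all label paths are disallowed")
  z
}

#' Negative log-likelihood of a label sequence
#'
#' `-log p(y | X) = log_partition - Score(X, y)`; always >= 0, and the
#' probabilities `exp(-loss)` over all sequences sum to 1.
#'
#' @inheritParams log_partition
#' @param y Integer label indices of the gold sequence.
#' @return Scalar loss.
#' @export
nll_loss <- function(S, T_mat, y, scheme = NULL, start = NULL,
                     stop = NULL) {
  log_partition(S, T_mat, scheme, start, stop) -
    sequence_score(S, T_mat, y, start, stop)
}

# Forward-backward in log space. Returns the unary marginals (n x k), the
# expected transition counts (k x k), expected start/stop indicators, and
# log Z — the ingredients of the NLL gradient.
crf_marginals <- function(S, T_mat, scheme = NULL, start = NULL,
                          stop = NULL) {
  n <- nrow(S); k <- ncol(S)
  masks <- scheme_masks(scheme, k)
  Tm <- T_mat + masks$T
  sv <- masks$start + (if (is.null(start)) 0 else start)
  ev <- masks$end + (if (is.null(stop)) 0 else stop)
  alpha <- matrix(-Inf, n, k)
  alpha[1, ] <- S[1, ] + sv
  if (n > 1) {
    for (i in 2:n) {
      for (j in seq_len(k)) {
        alpha[i, j] <- logsumexp(alpha[i - 1, ] + Tm[, j]) + S[i, j]
      }
    }
  }
  beta <- matrix(-Inf, n, k)
  beta[n, ] <- ev
  if (n > 1) {
    for (i in (n - 1):1) {
      for (j in seq_len(k)) {
        beta[i, j] <- logsumexp(Tm[j, ] + S[i + 1, ] + beta[i + 1, ])
      }
    }
  }
  logZ <- logsumexp(alpha[n, ] + ev)
  if (!is.finite(logZ)) stop_emrkg("all label paths are disallowed")
  unary <- exp(alpha + beta - logZ)
  pair <- matrix(0, k, k)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      lp <- outer(alpha[i, ], rep(1, k)) + Tm +
        outer(rep(1, k), S[i + 1, ] + beta[i + 1, ]) - logZ
      pair <- pair + exp(lp)
    }
  }
  p_start <- exp(alpha[1, ] + beta[1, ] - logZ)
  p_stop <- exp(alpha[n, ] + ev - logZ)
  list(unary = unary, pair = pair, p_start = p_start, p_stop = p_stop,
       logZ = logZ)
}

#' Viterbi decoding
#'
#' Finds the label sequence attaining the maximum score among all
#' sequences allowed by `scheme` (argmax of [sequence_score()]); with
#' constraints enabled the decoded sequence is always BIO-valid. Ties are
#' broken deterministically toward the lowest label index at every step.
#'
#' @inheritParams log_partition
#' @return List with `path` (integer label indices) and `score`
#'   (its [sequence_score()] including any boundary scores).
#' @export
viterbi_decode <- function(S, T_mat, scheme = NULL, start = NULL,
                           stop = NULL) {
  n <- nrow(S); k <- ncol(S)
  masks <- scheme_masks(scheme, k)
  Tm <- T_mat + masks$T
  delta <- S[1, ] + masks$start + (if (is.null(start)) 0 else start)
  back <- matrix(0L, n, k)
  if (n > 1) {
    for (i in 2:n) {
      prev <- delta
      for (j in seq_len(k)) {
        cand <- prev + Tm[, j]
        b <- which.max(cand) # first maximum = lowest index
        back[i, j] <- b
        delta[j] <- cand[b] + S[i, j]
      }
    }
  }
  final <- delta + masks$end + (if (is.null(stop)) 0 else stop)
  if (!is.finite(max(final))) stop_emrkg("all label paths are disallowed")
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1) {
    for (i in n:2) path[i - 1] <- back[i, path[i]]
  }
  list(path = path, score = sequence_score(S, T_mat, path, start, stop))
}
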