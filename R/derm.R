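# Dynamic Entity Replacement and Masking (DERM): a stochastic training-set
# augmentation for sequence labeling. Per sequence, one random number RN in
# (0,1) selects a branch: RN < 0.3 replaces every entity mention's surface
# with a same-type dictionary term; 0.3 <= RN < 0.6 masks every entity
# token; RN >= 0.6 leaves the sequence unchanged. Non-entity tokens are
# never touched.

#' DERM configuration
#'
#' @param dictionaries Named list of same-type replacement term lists
#'   (one character vector per entity type), e.g. from
#'   [generate_dictionaries()].
#' @param replace_threshold RN below this selects the replacement branch
#'   (default 0.3).
#' @param mask_threshold RN in `[replace_threshold, mask_threshold)`
#'   selects the masking branch (default 0.6); above it the sequence is
#'   kept as is.
#' @param mask_token Mask surface form (default `"[MASK]"`).
#' @param per_mention If `TRUE`, an independent RN is drawn per entity
#'   mention instead of one per sequence (default `FALSE`: the per-sequence
#'   RN governs all mentions uniformly).
#' @param seed Integer seed used by [augment_corpus()].
#' @return Object of class `derm_config`.
#' @export
derm_config <- function(dictionaries = list(), replace_threshold = 0.3,
                        mask_threshold = 0.6, mask_token = "[MASK]",
                        per_mention = FALSE, seed = 1L) {
  stopifnot(replace_threshold >= 0, mask_threshold <= 1,
            replace_threshold <= mask_threshold)
  structure(list(dictionaries = dictionaries,
                 replace_threshold = replace_threshold,
                 mask_threshold = mask_threshold,
                 mask_token = mask_token, per_mention = per_mention,
                 seed = as.integer(seed)),
            class = "derm_config")
}

# maximal B-x (I-x)* runs: data.frame(from, to, type)
entity_mentions <- function(labels) {
  from <- integer(); to <- integer(); type <- character()
  i <- 1L
  while (i <= length(labels)) {
    if (labels[i] != "O") {
      tp <- sub("^[BI]-", "", labels[i])
      j <- i
      while (j < length(labels) && labels[j + 1L] == paste0("I-", tp)) {
        j <- j + 1L
      }
      from <- c(from, i); to <- c(to, j); type <- c(type, tp)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(from = from, to = to, type = type, stringsAsFactors = FALSE)
}

#' Apply one DERM draw to a tag sequence
#'
#' The branch is selected by `rng_value` (injectable so every branch is
#' unit-testable deterministically; drawn from the current RNG when
#' omitted).
#'
#' * **replace** (`rng_value < replace_threshold`): every entity mention's
#'   surface is replaced by a uniformly drawn same-type dictionary term
#'   (excluding the original surface when alternatives exist); the new
#'   surface is re-tokenized per character and labels are re-aligned —
#'   `B-` on the first token, `I-` on the rest — so sequence length may
#'   change.
#' * **mask** (`replace_threshold <= rng_value < mask_threshold`): every
#'   entity token becomes `mask_token`; labels are unchanged
#'   (length-preserving, one mask per original entity token).
#' * **keep** (`rng_value >= mask_threshold`): the sequence is returned
#'   unchanged.
#'
#' Output is always BIO-valid; tokens labeled `"O"` are never modified.
#'
#' @param seq A BIO-valid [tag_sequence()].
#' @param cfg A [derm_config()]. The replacement branch requires a
#'   non-empty dictionary for every entity type present.
#' @param rng_value Optional fraction in `[0,1)` overriding the RN draw
#'   (with `per_mention = TRUE`, recycled over mentions).
#' @return A [tag_sequence()]; the branch taken is recorded in
#'   `attr(, "branch")` (`"replace"`, `"mask"`, or `"keep"`).
#' @export
derm_transform <- function(seq, cfg, rng_value = NULL) {
  stopifnot(inherits(seq, "tag_sequence"), inherits(cfg, "derm_config"))
  mentions <- entity_mentions(seq$labels)
  if (cfg$per_mention && nrow(mentions)) {
    rns <- if (is.null(rng_value)) {
      stats::runif(nrow(mentions))
    } else rep_len(rng_value, nrow(mentions))
  } else {
    rn <- if (is.null(rng_value)) stats::runif(1) else rng_value
    rns <- rep(rn, max(nrow(mentions), 1L))
  }
  branch_of <- function(rn) {
    if (rn < cfg$replace_threshold) "replace"
    else if (rn < cfg$mask_threshold) "mask"
    else "keep"
  }
  seq_branch <- branch_of(rns[1])
  if (!nrow(mentions)) {
    out <- seq
    attr(out, "branch") <- seq_branch
    return(out)
  }
  tokens <- seq$labels # placeholder; rebuilt below
  new_tokens <- list(); new_labels <- list()
  prev_end <- 0L
  # walk tokens, rewriting each mention according to its branch
  cursor <- 1L
  for (m in seq_len(nrow(mentions))) {
    br <- branch_of(rns[m])
    from <- mentions$from[m]; to <- mentions$to[m]; tp <- mentions$type[m]
    if (from > cursor) {
      idx <- cursor:(from - 1L)
      new_tokens[[length(new_tokens) + 1L]] <- seq$tokens[idx]
      new_labels[[length(new_labels) + 1L]] <- seq$labels[idx]
    }
    if (br == "replace") {
      dict <- cfg$dictionaries[[tp]]
      if (is.null(dict) || !length(dict)) {
        stop_emrkg("replacement branch needs a non-empty dictionary for type %s",
                   tp)
      }
      surface <- paste(seq$tokens[from:to], collapse = "")
      pool <- setdiff(dict, surface)
      if (!length(pool)) pool <- dict
      term <- if (length(pool) == 1) pool else sample(pool, 1)
      tk <- chars(term)
      new_tokens[[length(new_tokens) + 1L]] <- tk
      new_labels[[length(new_labels) + 1L]] <-
        c(paste0("B-", tp), rep(paste0("I-", tp), length(tk) - 1L))
    } else if (br == "mask") {
      new_tokens[[length(new_tokens) + 1L]] <-
        rep(cfg$mask_token, to - from + 1L)
      new_labels[[length(new_labels) + 1L]] <- seq$labels[from:to]
    } else {
      new_tokens[[length(new_tokens) + 1L]] <- seq$tokens[from:to]
      new_labels[[length(new_labels) + 1L]] <- seq$labels[from:to]
    }
    cursor <- to + 1L
  }
  if (cursor <= length(seq$tokens)) {
    idx <- cursor:length(seq$tokens)
    new_tokens[[length(new_tokens) + 1L]] <- seq$tokens[idx]
    new_labels[[length(new_labels) + 1L]] <- seq$labels[idx]
  }
  out <- tag_sequence(unlist(new_tokens), unlist(new_labels))
  attr(out, "branch") <- if (cfg$per_mention) "per_mention" else seq_branch
  out
}

#' Augment a corpus with DERM
#'
#' Draws one RN per sequence (per pass) and applies [derm_transform()].
#' Deterministic given `cfg$seed`; the decision for every sequence is
#' recorded in the branch log. Re-sampling the augmentation each training
#' epoch is achieved by calling this once per epoch with `pass` set to the
#' epoch number (each pass has its own derived seed).
#'
#' @param seqs List of [tag_sequence()] objects.
#' @param cfg A [derm_config()].
#' @param pass Pass number mixed into the seed (default 1).
#' @return List of augmented sequences with attribute `"branch_log"`: a
#'   character vector, one branch name per input sequence.
#' @export
augment_corpus <- function(seqs, cfg, pass = 1L) {
  stopifnot(inherits(cfg, "derm_config"))
  withr::with_seed(cfg$seed + 7919L * (as.integer(pass) - 1L), {
    out <- vector("list", length(seqs))
    log <- character(length(seqs))
    for (i in seq_along(seqs)) {
      out[[i]] <- derm_transform(seqs[[i]], cfg)
      log[i] <- attr(out[[i]], "branch")
    }
    attr(out, "branch_log") <- log
    out
  })
}
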