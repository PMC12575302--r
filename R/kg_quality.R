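# Stratified triple sampling and triple-accuracy computation with
# insufficient-context exclusion.
#
# Each sampled triple receives an expert label in {Correct, Incorrect,
# InsufficientContext}. The evaluable count is n_eff = sampled - IC and
# triple accuracy is TAcc = x / n_eff where x counts Correct labels;
# IC items are excluded from the ratio and their proportion is reported
# separately as a documentation-completeness indicator.

qa_label_levels <- c("Correct", "Incorrect", "InsufficientContext")

#' Stratified random sample of triples
#'
#' Draws the requested number of triples per relation stratum, uniformly
#' without replacement, deterministic given `seed`. Strata of size 0 are
#' absent from the sample; a stratum with fewer triples than requested is
#' an error naming it.
#'
#' @param store A `triple_store` from [assemble_kg()].
#' @param strata_sizes Named integer vector: requested triples per
#'   relation (the audit defaults to 500 triples over the five major
#'   relation types: 160 has_symptom, 110 accompany_with, 90
#'   recommand_drug, 80 recommand_eat, 60 rels_diseases).
#' @param seed Integer seed.
#' @return data.frame (`triple_id`, `subject`, `relation`, `object`,
#'   `stratum`, `label`) with `label` `NA` — to be filled by annotators or
#'   [generate_qa_labels()]-style simulation.
#' @export
stratified_sample <- function(store,
                              strata_sizes = c(has_symptom = 160L,
                                               accompany_with = 110L,
                                               recommand_drug = 90L,
                                               recommand_eat = 80L,
                                               rels_diseases = 60L),
                              seed = 1L) {
  stopifnot(inherits(store, "triple_store"), !is.null(names(strata_sizes)))
  strata_sizes <- strata_sizes[strata_sizes > 0]
  withr::with_seed(seed, {
    rows <- lapply(names(strata_sizes), function(rel) {
      pool <- store$triples[store$triples$relation == rel, , drop = FALSE]
      n_req <- strata_sizes[[rel]]
      if (nrow(pool) < n_req) {
        stop_emrkg("stratum %s has only %d triples (requested %d)",
                   rel, nrow(pool), n_req)
      }
      pool <- pool[sample.int(nrow(pool), n_req), , drop = FALSE]
      data.frame(subject = pool$subject, relation = pool$relation,
                 object = pool$object, stratum = rel,
                 label = NA_character_, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(triple_id = sprintf("q%04d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Triple accuracy with insufficient-context exclusion
#'
#' Computes, per stratum and overall, the sampled count, the
#' insufficient-context (IC) count, the evaluable count
#' `n_eff = sampled - IC`, the correct count `x`, and the accuracy
#' `TAcc = x / n_eff`. The overall row pools the counts (it is the pooled
#' ratio, not the mean of stratum accuracies). Percentages are rounded
#' half-up to 2 decimals for display; full precision is retained in the
#' `accuracy` column. A stratum with `n_eff = 0` has undefined accuracy,
#' reported as `NA`.
#'
#' @param sample data.frame with columns `stratum` and `label` (every item
#'   labeled `Correct`, `Incorrect`, or `InsufficientContext`), e.g. an
#'   annotated [stratified_sample()] or [generate_qa_labels()] output.
#' @return Object of class `qa_result`: a data.frame with one row per
#'   stratum plus an `Overall` row; columns `stratum`, `sampled`, `ic`,
#'   `n_eff`, `correct`, `incorrect`, `accuracy` (fraction or `NA`),
#'   `accuracy_pct` (2-decimal percent), `ic_pct`.
#' @examples
#' s <- generate_qa_labels(c(has_symptom = 50L), qa_accuracy = 1,
#'                         ic_rate = 0, seed = 1)
#' triple_accuracy(s)
#' @export
triple_accuracy <- function(sample) {
  stopifnot(is.data.frame(sample),
            all(c("stratum", "label") %in% names(sample)))
  if (anyNA(sample$label)) stop_emrkg("every sampled triple must be labeled")
  bad <- setdiff(unique(sample$label), qa_label_levels)
  if (length(bad)) {
    stop_emrkg("unknown label(s): %s (expected %s)",
               paste(bad, collapse = ", "),
               paste(qa_label_levels, collapse = ", "))
  }
  one <- function(labels, name) {
    sampled <- length(labels)
    ic <- sum(labels == "InsufficientContext")
    x <- sum(labels == "Correct")
    n_eff <- sampled - ic
    acc <- if (n_eff > 0) x / n_eff else NA_real_
    data.frame(stratum = name, sampled = sampled, ic = ic, n_eff = n_eff,
               correct = x, incorrect = n_eff - x, accuracy = acc,
               accuracy_pct = if (is.na(acc)) NA_real_ else
                 round_half_up(100 * acc, 2),
               ic_pct = round_half_up(100 * ic / sampled, 2),
               stringsAsFactors = FALSE)
  }
  strata <- unique(sample$stratum)
  rows <- lapply(strata, function(st) {
    one(sample$label[sample$stratum == st], st)
  })
  rows[[length(rows) + 1L]] <- one(sample$label, "Overall")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qa_result", "data.frame")
  out
}

#' Build a labeled QA sample from printed audit counts
#'
#' Reconstructs a per-stratum labeled sample from summary counts
#' (sampled, insufficient-context, correct), e.g. the rows of a published
#' audit table, so [triple_accuracy()] can recompute the reported
#' percentages from the raw labels.
#'
#' @param counts data.frame with columns `stratum`, `sampled`, `ic`,
#'   `correct`.
#' @return A labeled sample data.frame for [triple_accuracy()].
#' @export
qa_sample_from_counts <- function(counts) {
  stopifnot(all(c("stratum", "sampled", "ic", "correct") %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], {
      incorrect <- sampled - ic - correct
      stopifnot(incorrect >= 0)
      data.frame(stratum = stratum,
                 label = c(rep("Correct", correct),
                           rep("Incorrect", incorrect),
                           rep("InsufficientContext", ic)),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  cbind(triple_id = sprintf("q%04d", seq_len(nrow(out))),
        subject = NA_character_, relation = out$stratum,
        object = NA_character_, out)
}
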