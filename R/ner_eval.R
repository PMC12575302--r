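# Exact-match entity evaluation: TP/FP/FN counting under (type, start,
# end) equality and precision / recall / F1.

#' Match counts
#'
#' @param tp,fp,fn Non-negative integers. `tp + fn` equals the number of
#'   gold entities, `tp + fp` the number of predicted entities.
#' @return Object of class `match_counts`.
#' @export
match_counts <- function(tp = 0L, fp = 0L, fn = 0L) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("<match_counts tp=%d fp=%d fn=%d>\n", x$tp, x$fp, x$fn))
  invisible(x)
}

span_keys <- function(spans) {
  if (!nrow(spans)) return(character())
  doc <- if ("doc_id" %in% names(spans)) spans$doc_id else ""
  unique(paste(doc, spans$entity_type, spans$start, spans$end, sep = "\r"))
}

#' Exact-match entity counting
#'
#' A predicted entity is a true positive only when a gold entity has the
#' same type AND the same boundaries; a prediction with the right boundary
#' but the wrong type (or vice versa) counts as one false positive plus
#' one false negative. Span sets are deduplicated before counting.
#'
#' @param pred,gold Span data.frames (`entity_type`, `start`, `end`,
#'   optional `doc_id` to scope matching per document).
#' @param by_type If `TRUE`, also return per-type counts.
#' @return A [match_counts()]; with `by_type`, the per-type breakdown in
#'   `attr(, "per_type")`.
#' @export
match_entities <- function(pred, gold, by_type = FALSE) {
  pk <- span_keys(pred)
  gk <- span_keys(gold)
  tp <- length(intersect(pk, gk))
  out <- match_counts(tp, length(pk) - tp, length(gk) - tp)
  if (by_type) {
    types <- sort(unique(c(pred$entity_type, gold$entity_type)))
    per <- lapply(types, function(tt) {
      match_entities(pred[pred$entity_type == tt, , drop = FALSE],
                     gold[gold$entity_type == tt, , drop = FALSE])
    })
    names(per) <- types
    attr(out, "per_type") <- per
  }
  out
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, reported as
#' percentages. A zero denominator yields 0 with a warning (the convention
#' for empty prediction or gold sets).
#'
#' @param counts A [match_counts()].
#' @return Named numeric vector `c(precision, recall, f1)` in percent
#'   (full precision; round for display).
#' @examples
#' prf(match_counts(tp = 149, fp = 9, fn = 11))
#' @export
prf <- function(counts) {
  stopifnot(inherits(counts, "match_counts"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s denominator is 0; value defined as 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  p <- 100 * safe_div(counts$tp, counts$tp + counts$fp, "precision")
  r <- 100 * safe_div(counts$tp, counts$tp + counts$fn, "recall")
  f1 <- if (p + r == 0) {
    if (counts$tp + counts$fp + counts$fn > 0) {
      warning("precision + recall is 0; F1 defined as 0", call. = FALSE)
    }
    0
  } else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Per-type and micro-averaged evaluation report
#'
#' Micro averaging pools the counts over types (the default aggregate);
#' the per-type rows give the macro-style breakdown.
#'
#' @inheritParams match_entities
#' @return data.frame with one row per entity type plus a `micro` row:
#'   columns `entity_type`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   (percent, 2 decimals).
#' @export
evaluate_entities <- function(pred, gold) {
  m <- match_entities(pred, gold, by_type = TRUE)
  per <- attr(m, "per_type")
  rows <- lapply(names(per), function(tt) {
    met <- suppressWarnings(prf(per[[tt]]))
    data.frame(entity_type = tt, tp = per[[tt]]$tp, fp = per[[tt]]$fp,
               fn = per[[tt]]$fn,
               precision = round_half_up(met["precision"]),
               recall = round_half_up(met["recall"]),
               f1 = round_half_up(met["f1"]), stringsAsFactors = FALSE)
  })
  met <- suppressWarnings(prf(m))
  rows[[length(rows) + 1L]] <-
    data.frame(entity_type = "micro", tp = m$tp, fp = m$fp, fn = m$fn,
               precision = round_half_up(met["precision"]),
               recall = round_half_up(met["recall"]),
               f1 = round_half_up(met["f1"]), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
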