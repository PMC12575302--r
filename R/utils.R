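#' emrkg: clinical EMR knowledge-graph construction
#'
#' Pipeline stages: BRAT/BIO corpus I/O ([parse_ann()], [spans_to_bio()]),
#' synthetic EMR generation ([generate_corpus()]), DERM augmentation
#' ([derm_transform()]), a toy transformer encoder ([encode()]), a
#' BiLSTM-CRF sequence labeler ([fit_labeler()], [viterbi_decode()]),
#' exact-match evaluation ([match_entities()]), TF-IDF knowledge fusion
#' ([map_entity()]), triple assembly and export ([assemble_kg()]),
#' and triple-accuracy quality auditing ([triple_accuracy()]).
#'
#' @keywords internal
"_PACKAGE"

# Numerically stable log(sum(exp(x))); tolerates -Inf entries (zero mass).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m) # all -Inf (or contains +Inf/NaN upstream)
  m + log(sum(exp(x - m)))
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() uses round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Harmonic-mean F1 from precision and recall
#'
#' Computes `2 * P * R / (P + R)`. Inputs may be fractions or percentages;
#' the result is on the same scale. Returns 0 with a warning when
#' `P + R == 0`.
#'
#' @param precision,recall Non-negative scalars on a common scale.
#' @return Scalar F1 on the input scale.
#' @examples
#' f1_score(94.69, 93.24)
#' @export
f1_score <- function(precision, recall) {
  stopifnot(is.numeric(precision), is.numeric(recall),
            precision >= 0, recall >= 0)
  if (precision + recall == 0) {
    warning("precision + recall is 0; F1 defined as 0")
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

# Characters of a string, UTF-8 aware.
chars <- function(x) strsplit(x, "", fixed = FALSE)[[1]]

# substring by 0-based, end-exclusive character offsets (BRAT convention)
substr0 <- function(text, start, end) substring(text, start + 1, end)

stop_emrkg <- function(...) stop(sprintf(...), call. = FALSE)
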