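# Synthetic EMR generator: typed dictionaries, annotated pseudo-EMR
# corpora with exact gold spans, surface-variant query/reference pairs for
# fusion testing, and labeled triple samples for QA testing.
#
# Generated text uses CJK-range placeholder characters: each entity type
# draws from its own disjoint 64-character block (a deliberately strong
# lexical cue), carrier text from a separate filler block. No real
# clinical text is involved.

#' Generator configuration
#'
#' Study conditions for the synthetic EMR corpus. All generators are pure
#' functions of `(config, seed)`: they restore the global RNG state on
#' exit and are bit-reproducible for a given seed.
#'
#' @param n_docs Number of documents.
#' @param entity_types Entity types to generate dictionaries and mentions
#'   for. Default: the four dictionary types used by DERM augmentation.
#' @param dict_sizes Named integer vector of terms per type; a single
#'   unnamed value recycles over `entity_types`.
#' @param mentions_per_doc Entity mentions per document (exact count).
#' @param type_weights Multinomial weights over `entity_types` for mention
#'   types; default uniform.
#' @param term_len_range Inclusive character-length range of dictionary
#'   terms.
#' @param variant_rules Surface-edit rules for [generate_variant_pairs()];
#'   see [default_variant_rules()].
#' @param qa_accuracy Probability that an evaluable generated triple is
#'   labeled Correct (default 0.935).
#' @param ic_rate Probability of an Insufficient Context label
#'   (default 0.02).
#' @param seed Integer seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_docs = 100L,
                             entity_types = c("disease", "symptom",
                                              "treatment_options",
                                              "examination"),
                             dict_sizes = 120L,
                             mentions_per_doc = 3L,
                             type_weights = NULL,
                             term_len_range = c(2L, 10L),
                             variant_rules = default_variant_rules(),
                             qa_accuracy = 0.935,
                             ic_rate = 0.02,
                             seed = 1L) {
  if (is.null(names(dict_sizes))) {
    dict_sizes <- stats::setNames(rep(as.integer(dict_sizes),
                                      length.out = length(entity_types)),
                                  entity_types)
  }
  if (is.null(type_weights)) {
    type_weights <- stats::setNames(rep(1, length(entity_types)),
                                    entity_types)
  }
  stopifnot(all(entity_types %in% names(dict_sizes)),
            all(dict_sizes[entity_types] > 0),
            qa_accuracy >= 0, qa_accuracy <= 1,
            ic_rate >= 0, ic_rate <= 1,
            mentions_per_doc >= 1,
            term_len_range[1] >= 1, term_len_range[2] >= term_len_range[1])
  structure(list(n_docs = as.integer(n_docs), entity_types = entity_types,
                 dict_sizes = dict_sizes,
                 mentions_per_doc = as.integer(mentions_per_doc),
                 type_weights = type_weights,
                 term_len_range = as.integer(term_len_range),
                 variant_rules = variant_rules,
                 qa_accuracy = qa_accuracy, ic_rate = ic_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Disjoint CJK character blocks: one 64-char block per entity type
# (starting at U+4E00, stride 80), one filler block for carrier text.
type_alphabet <- function(type_index) {
  intToUtf8(0x4E00 + (type_index - 1L) * 80L + 0:63, multiple = TRUE)
}

filler_alphabet <- function() intToUtf8(0x5B00 + 0:47, multiple = TRUE)

#' Generate per-type entity dictionaries
#'
#' Produces `dict_sizes[type]` unique terms per entity type. Each type
#' draws characters from its own disjoint CJK-range block, so terms of
#' different types share no characters; term lengths are sampled uniformly
#' from `term_len_range` (with both endpoints forced to appear when the
#' dictionary is large enough, so the length distribution covers the whole
#' range).
#'
#' @param cfg A [generator_config()].
#' @return Named list of character vectors, one per entity type.
#' @export
generate_dictionaries <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    out <- lapply(seq_along(cfg$entity_types), function(ti) {
      type <- cfg$entity_types[ti]
      alpha <- type_alphabet(ti)
      size <- cfg$dict_sizes[[type]]
      lens <- sample(seq(cfg$term_len_range[1], cfg$term_len_range[2]),
                     size, replace = TRUE)
      span <- cfg$term_len_range[2] - cfg$term_len_range[1]
      if (size >= 2 && span > 0) { # guarantee coverage of the range ends
        lens[1] <- cfg$term_len_range[1]
        lens[2] <- cfg$term_len_range[2]
      }
      terms <- character(0)
      for (L in lens) {
        repeat {
          term <- paste(sample(alpha, L, replace = TRUE), collapse = "")
          if (!term %in% terms) break
        }
        terms <- c(terms, term)
      }
      terms
    })
    names(out) <- cfg$entity_types
    out
  })
}

#' Generate an annotated pseudo-EMR corpus
#'
#' Each document embeds `mentions_per_doc` dictionary terms (types drawn
#' from the configured multinomial) in filler carrier text, ending with a
#' CJK full stop. Gold spans are recorded exactly during construction:
#' every span's surface is a dictionary term of its type, so downstream
#' statistics can be audited against generator bookkeeping.
#'
#' @param cfg A [generator_config()].
#' @param dicts Dictionaries from [generate_dictionaries()].
#' @param filler_range Inclusive range of filler-run lengths between
#'   mentions.
#' @return List of [annotated_document()] objects; each carries the drawn
#'   mention types in `attr(doc, "gold_types")`.
#' @export
generate_corpus <- function(cfg, dicts = generate_dictionaries(cfg),
                            filler_range = c(2L, 5L)) {
  stopifnot(inherits(cfg, "generator_config"))
  missing <- setdiff(cfg$entity_types, names(dicts))
  if (length(missing) || any(!lengths(dicts[cfg$entity_types]))) {
    stop_emrkg("empty or missing dictionary for type(s): %s",
               paste(c(missing,
                       cfg$entity_types[!lengths(dicts[cfg$entity_types])]),
                     collapse = ", "))
  }
  fill <- filler_alphabet()
  withr::with_seed(cfg$seed + 1L, {
    lapply(seq_len(cfg$n_docs), function(di) {
      types <- sample(cfg$entity_types, cfg$mentions_per_doc,
                      replace = TRUE,
                      prob = cfg$type_weights[cfg$entity_types])
      terms <- vapply(types, function(tp) sample(dicts[[tp]], 1),
                      character(1))
      text <- ""
      spans <- empty_spans()
      for (k in seq_along(terms)) {
        run <- sample(seq(filler_range[1], filler_range[2]), 1)
        text <- paste0(text,
                       paste(sample(fill, run, replace = TRUE),
                             collapse = ""))
        start <- nchar(text)
        text <- paste0(text, terms[k])
        spans[nrow(spans) + 1L, ] <- list(sprintf("T%d", k), types[k],
                                          start, nchar(text), terms[k])
      }
      text <- paste0(text, "。")
      doc <- annotated_document(sprintf("doc%04d", di), text, spans)
      attr(doc, "gold_types") <- types
      doc
    })
  })
}

#' Default surface-variant rules
#'
#' Light terminal edits emulating clinician recording habits (affix
#' variation at the end of a term, occasional verbatim reuse):
#' `identity` (weight 0.1), `drop_last` (0.3), `append_char` (0.3, adds a
#' character from the term's own alphabet), `substitute_last` (0.3).
#' Each rule is a named list with a `name`, a sampling `weight`, and an
#' `apply(term, alphabet)` function returning the edited surface.
#'
#' @return List of rules for [generate_variant_pairs()].
#' @export
default_variant_rules <- function() {
  list(
    list(name = "identity", weight = 0.1,
         apply = function(term, alphabet) term),
    list(name = "drop_last", weight = 0.3,
         apply = function(term, alphabet) {
           substr(term, 1, nchar(term) - 1)
         }),
    list(name = "append_char", weight = 0.3,
         apply = function(term, alphabet) {
           paste0(term, sample(alphabet, 1))
         }),
    list(name = "substitute_last", weight = 0.3,
         apply = function(term, alphabet) {
           last <- substr(term, nchar(term), nchar(term))
           repl <- sample(setdiff(alphabet, last), 1)
           paste0(substr(term, 1, nchar(term) - 1), repl)
         })
  )
}

#' Generate query / canonical variant pairs for fusion testing
#'
#' Samples dictionary terms (of length >= `min_len`, so edits stay light
#' relative to the term) and perturbs each with one rule drawn by weight.
#' The applied rule is logged per pair, giving fusion accuracy an exact
#' gold standard.
#'
#' @param dicts Dictionaries from [generate_dictionaries()].
#' @param variant_rules Rule list, see [default_variant_rules()].
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param type Entity type whose dictionary is sampled (default first).
#' @param min_len Minimum length of source terms.
#' @return data.frame with columns `query`, `gold`, `rule`.
#' @export
generate_variant_pairs <- function(dicts,
                                   variant_rules = default_variant_rules(),
                                   n = 500L, seed = 1L,
                                   type = names(dicts)[1], min_len = 4L) {
  terms <- dicts[[type]]
  terms <- terms[nchar(terms) >= min_len]
  if (!length(terms)) stop_emrkg("no terms of length >= %d in %s", min_len, type)
  alphabet <- sort(unique(unlist(strsplit(dicts[[type]], ""))))
  weights <- vapply(variant_rules, function(r) r$weight, numeric(1))
  withr::with_seed(seed, {
    golds <- sample(terms, n, replace = TRUE)
    rule_idx <- sample(seq_along(variant_rules), n, replace = TRUE,
                       prob = weights)
    queries <- vapply(seq_len(n), function(i) {
      variant_rules[[rule_idx[i]]]$apply(golds[i], alphabet)
    }, character(1))
    data.frame(query = queries, gold = golds,
               rule = vapply(variant_rules, function(r) r$name,
                             character(1))[rule_idx],
               stringsAsFactors = FALSE)
  })
}

#' Generate a labeled triple sample for QA testing
#'
#' Emulates expert triple auditing: for each relation stratum, generates
#' the requested number of synthetic triples and assigns each a label —
#' `InsufficientContext` with probability `ic_rate`, otherwise `Correct`
#' with probability `qa_accuracy` and `Incorrect` with the remainder. As
#' counts grow, label proportions converge to
#' `(accuracy * (1 - ic), (1 - accuracy) * (1 - ic), ic)`.
#'
#' @param strata Named integer vector: triples to generate per relation.
#' @param qa_accuracy,ic_rate Label probabilities, see above.
#' @param seed Integer seed.
#' @return data.frame with columns `triple_id`, `subject`, `relation`,
#'   `object`, `stratum`, `label` — the layout consumed by
#'   [triple_accuracy()].
#' @export
generate_qa_labels <- function(strata = c(has_symptom = 160L,
                                          accompany_with = 110L,
                                          recommand_drug = 90L,
                                          recommand_eat = 80L,
                                          rels_diseases = 60L),
                               qa_accuracy = 0.935, ic_rate = 0.02,
                               seed = 1L) {
  stopifnot(!is.null(names(strata)), all(strata >= 0))
  strata <- strata[strata > 0]
  withr::with_seed(seed, {
    rows <- lapply(names(strata), function(rel) {
      n <- strata[[rel]]
      ic <- stats::runif(n) < ic_rate
      correct <- stats::runif(n) < qa_accuracy
      label <- ifelse(ic, "InsufficientContext",
                      ifelse(correct, "Correct", "Incorrect"))
      data.frame(subject = sprintf("S_%s_%03d", rel, seq_len(n)),
                 relation = rel,
                 object = sprintf("O_%s_%03d", rel, seq_len(n)),
                 stratum = rel, label = label, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(triple_id = sprintf("q%04d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}
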