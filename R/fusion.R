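# Knowledge fusion: normalizing variant entity surface forms against
# reference terminologies by character n-gram TF-IDF cosine similarity,
# with a three-tier mapping (automatic / manual review / reject).
#
# Each reference term is one document d. TF(t, d) = f_{t,d} / f_d (count
# of feature t in d over the total feature count of d); IDF(t) =
# log(N / |{d : t in d}|) with the natural log and, by default, no
# smoothing. TF-IDF(t, d) = TF * IDF; similarity is the cosine of the
# weighted vectors.

char_ngrams <- function(term, ngram_range) {
  cs <- chars(term)
  L <- length(cs)
  out <- character()
  for (n in seq(ngram_range[1], ngram_range[2])) {
    if (L >= n) {
      out <- c(out, vapply(seq_len(L - n + 1L), function(i) {
        paste(cs[i:(i + n - 1L)], collapse = "")
      }, character(1)))
    }
  }
  out
}

#' Fit a TF-IDF model on a reference terminology
#'
#' Each canonical term is treated as one document; features are character
#' n-grams. TF is the feature count divided by the document's total
#' feature count (so the TF values within a document sum to 1); IDF is the
#' natural log of `N` over the document frequency, unsmoothed by default,
#' so a feature occurring in every reference term gets weight 0.
#'
#' @param reference_terms Character vector of canonical terms (at least
#'   one non-empty).
#' @param ngram_range Inclusive n-gram size range, default `c(1, 2)`.
#' @param smooth Add-one document-frequency smoothing
#'   (`log(N / (df + 1))` floored at 0); default off, i.e. the plain
#'   formula.
#' @return Object of class `tfidf_model`: `vocabulary`, `idf`,
#'   `reference_terms`, the reference vectors (rows of `ref_matrix`), and
#'   `ngram_range`.
#' @export
fit_tfidf <- function(reference_terms, ngram_range = c(1L, 2L),
                      smooth = FALSE) {
  reference_terms <- reference_terms[nzchar(reference_terms)]
  if (!length(reference_terms)) stop_emrkg("empty reference corpus")
  reference_terms <- unique(reference_terms)
  docs <- lapply(reference_terms, char_ngrams, ngram_range = ngram_range)
  vocabulary <- sort(unique(unlist(docs)))
  nfeat <- length(vocabulary)
  N <- length(docs)
  df <- integer(nfeat)
  tf <- matrix(0, N, nfeat, dimnames = list(reference_terms, vocabulary))
  for (i in seq_len(N)) {
    tab <- table(docs[[i]])
    j <- match(names(tab), vocabulary)
    tf[i, j] <- as.numeric(tab) / length(docs[[i]])
    df[j] <- df[j] + 1L
  }
  idf <- if (smooth) pmax(log(N / (df + 1)), 0) else log(N / df)
  names(idf) <- vocabulary
  ref_matrix <- sweep(tf, 2, idf, `*`)
  structure(list(vocabulary = vocabulary, idf = idf,
                 reference_terms = reference_terms,
                 ref_matrix = ref_matrix, ngram_range = ngram_range,
                 smooth = smooth),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("<tfidf_model: %d reference terms, %d %d-%d-gram features>\n",
              length(x$reference_terms), length(x$vocabulary),
              x$ngram_range[1], x$ngram_range[2]))
  invisible(x)
}

#' Vectorize a term with a fitted TF-IDF model
#'
#' Component per vocabulary feature = the term's TF times the model's IDF.
#' Query features absent from the reference vocabulary are dropped (they
#' carry no reference-side weight); the TF denominator still counts every
#' feature of the query. An empty term yields a zero vector with a
#' warning.
#'
#' @param term Character scalar.
#' @param model A [fit_tfidf()] model.
#' @return Named numeric vector over the model vocabulary.
#' @export
vectorize <- function(term, model) {
  stopifnot(inherits(model, "tfidf_model"))
  v <- stats::setNames(numeric(length(model$vocabulary)),
                       model$vocabulary)
  if (!nzchar(term)) {
    warning("empty term; returning a zero vector", call. = FALSE)
    return(v)
  }
  feats <- char_ngrams(term, model$ngram_range)
  tab <- table(feats)
  j <- match(names(tab), model$vocabulary)
  keep <- !is.na(j)
  v[j[keep]] <- as.numeric(tab)[keep] / length(feats) * model$idf[j[keep]]
  v
}

#' Cosine similarity
#'
#' Dot product over the product of norms, defined as 0 when either vector
#' has zero norm; in `[0, 1]` for nonnegative vectors.
#'
#' @param v1,v2 Numeric vectors of equal length.
#' @return Scalar similarity.
#' @examples
#' cosine_sim(c(1, 2, 0), c(2, 1, 1)) # 4 / (sqrt(5) * sqrt(6))
#' @export
cosine_sim <- function(v1, v2) {
  if (length(v1) != length(v2)) stop_emrkg("vector dimension mismatch")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(v1 * v2) / (n1 * n2)
}

#' Map a query entity to a reference terminology
#'
#' Computes the cosine similarity between the query's TF-IDF vector and
#' every reference term (ties broken toward the lexicographically smallest
#' term) and assigns the three-tier decision: similarity strictly above
#' `auto_threshold` maps automatically; similarity in
#' `[review_threshold, auto_threshold]` (both ends inclusive) is queued
#' for manual review; anything below `review_threshold` is rejected as a
#' different entity. The tiers partition `[0, 1]`.
#'
#' @param query Query surface form.
#' @param model A [fit_tfidf()] reference model.
#' @param auto_threshold,review_threshold Tier cut points, defaults 0.75
#'   and 0.6; must satisfy `0 <= review <= auto <= 1`.
#' @return One-row data.frame (`query`, `best_match`, `similarity`,
#'   `tier`); `best_match` is `NA` in the reject tier.
#' @export
map_entity <- function(query, model, auto_threshold = 0.75,
                       review_threshold = 0.6) {
  stopifnot(review_threshold >= 0, auto_threshold <= 1,
            review_threshold <= auto_threshold)
  qv <- vectorize(query, model)
  sims <- apply(model$ref_matrix, 1, cosine_sim, v2 = qv)
  ord <- order(-sims, model$reference_terms, method = "radix")
  best <- ord[1]
  s <- sims[best]
  tier <- if (s > auto_threshold) "auto" else
    if (s >= review_threshold) "review" else "reject"
  data.frame(query = query,
             best_match = if (tier == "reject") NA_character_ else
               model$reference_terms[best],
             similarity = unname(s), tier = tier,
             stringsAsFactors = FALSE)
}

#' Map a batch of entities, routed by type to per-category references
#'
#' Implements reference routing: disease and symptom entities are matched
#' against the medical-website-style reference corpus, treatment and
#' operation-recording entities against the clinical-terminology-standard
#' reference. Entity types with no assigned reference pass through
#' unmapped in the reject tier (kept verbatim). The review tier can be
#' written out as a human-review queue; the pipeline never auto-merges
#' reviewed cases.
#'
#' @param entities data.frame with columns `entity_type`, `surface`.
#' @param models Named list of [fit_tfidf()] models (reference corpora).
#' @param routing Named character vector mapping entity type to a name in
#'   `models`; see [default_reference_routing()].
#' @param auto_threshold,review_threshold Passed to [map_entity()].
#' @param review_file Optional path; review-tier rows are appended as TSV.
#' @return data.frame: the input plus `best_match`, `similarity`, `tier`,
#'   `reference`, and `canonical` (the auto-tier mapped name, otherwise
#'   the original surface — mapping is idempotent on already-canonical
#'   sets).
#' @export
route_by_type <- function(entities, models,
                          routing = default_reference_routing(),
                          auto_threshold = 0.75, review_threshold = 0.6,
                          review_file = NULL) {
  stopifnot(is.data.frame(entities),
            all(c("entity_type", "surface") %in% names(entities)))
  assigned <- routing[entities$entity_type]
  known <- !is.na(assigned)
  bad <- unique(assigned[known][!assigned[known] %in% names(models)])
  if (length(bad)) {
    stop_emrkg("entity type(s) routed to missing reference corpus: %s",
               paste(bad, collapse = ", "))
  }
  out <- entities
  out$best_match <- NA_character_
  out$similarity <- 0
  out$tier <- "reject"
  out$reference <- unname(ifelse(known, assigned, NA_character_))
  for (i in which(known)) {
    d <- map_entity(out$surface[i], models[[assigned[i]]],
                    auto_threshold, review_threshold)
    out$best_match[i] <- d$best_match
    out$similarity[i] <- d$similarity
    out$tier[i] <- d$tier
  }
  out$canonical <- ifelse(out$tier == "auto", out$best_match, out$surface)
  if (!is.null(review_file)) {
    rq <- out[out$tier == "review", , drop = FALSE]
    utils::write.table(rq, review_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  out
}

#' Default entity-type -> reference-corpus routing
#'
#' Diseases and symptoms normalize against the `"website"` reference;
#' treatment options and operation recordings against the `"terminology"`
#' standard.
#'
#' @return Named character vector.
#' @export
default_reference_routing <- function() {
  c(disease = "website", symptom = "website",
    treatment_options = "terminology", operation_recording = "terminology")
}
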