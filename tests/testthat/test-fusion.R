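test_that("TF and IDF follow the per-term-document formulas", {
  # single document "AB", unigrams: TF = 0.5 each, IDF = log(1/1) = 0
  m1 <- fit_tfidf("AB", ngram_range = c(1, 1))
  expect_equal(unname(m1$idf), c(0, 0))
  expect_true(all(m1$ref_matrix == 0))
  # two documents: shared feature weighted 0, unique ones log 2
  m2 <- fit_tfidf(c("AB", "AC"), ngram_range = c(1, 1))
  expect_equal(m2$idf[["A"]], 0)
  expect_equal(m2$idf[["B"]], log(2))
  expect_equal(m2$idf[["C"]], log(2))
  expect_equal(m2$ref_matrix["AB", "B"], 0.5 * log(2))
  # TF within any document sums to 1 (checked through the raw counts)
  m3 <- fit_tfidf(c("ABAB", "CC", "ABC"))
  for (term in m3$reference_terms) {
    feats <- emrkg:::char_ngrams(term, m3$ngram_range)
    tf <- table(feats) / length(feats)
    expect_equal(sum(tf), 1)
  }
  expect_error(fit_tfidf(character()), "empty")
  # add-one smoothing floors IDF at zero instead of going negative
  ms <- fit_tfidf(c("AB", "AC"), ngram_range = c(1, 1), smooth = TRUE)
  expect_equal(ms$idf[["A"]], 0)
  expect_equal(ms$idf[["B"]], 0)
})

test_that("vectorize weighs query TF by reference IDF, dropping unseen", {
  m <- fit_tfidf(c("AB", "AC"), ngram_range = c(1, 1))
  # a reference term vectorizes to its own reference row
  expect_equal(vectorize("AB", m), m$ref_matrix["AB", ])
  # no shared features: zero vector
  expect_true(all(vectorize("XY", m) == 0))
  # hand case: query "ABC" has features A,B,C each TF 1/3
  v <- vectorize("ABC", m)
  expect_equal(v[["A"]], 0)
  expect_equal(v[["B"]], log(2) / 3)
  expect_equal(v[["C"]], log(2) / 3)
  expect_warning(v0 <- vectorize("", m), "empty")
  expect_true(all(v0 == 0))
})

test_that("cosine similarity handles identity, disjointness, zero norms", {
  expect_equal(cosine_sim(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 2, 0), c(2, 1, 1)),
               4 / (sqrt(5) * sqrt(6)), tolerance = 1e-12)
  expect_identical(cosine_sim(c(0, 0), c(1, 1)), 0)
  expect_error(cosine_sim(1:2, 1:3), "dimension")
})

test_that("map_entity tiers partition [0,1] with inclusive review bounds", {
  cfg <- generator_config(seed = 19)
  dicts <- generate_dictionaries(cfg)
  m <- fit_tfidf(dicts$disease)
  # identical query: similarity exactly 1, auto tier
  d <- map_entity(dicts$disease[5], m)
  expect_equal(d$similarity, 1)
  expect_identical(d$tier, "auto")
  expect_identical(d$best_match, dicts$disease[5])
  # boundary semantics around a real similarity value s
  q <- paste0(substr(dicts$disease[7], 1, nchar(dicts$disease[7]) - 1))
  s <- map_entity(q, m)$similarity
  expect_identical(map_entity(q, m, auto_threshold = s,
                              review_threshold = 0)$tier, "review")
  expect_identical(map_entity(q, m, auto_threshold = s,
                              review_threshold = s)$tier, "review")
  expect_identical(map_entity(q, m, auto_threshold = 1,
                              review_threshold = min(1, s + 1e-6))$tier,
                   "reject")
  expect_true(is.na(map_entity(q, m, auto_threshold = 1,
                               review_threshold = min(1, s + 1e-6))$best_match))
  # every similarity lands in exactly one tier
  sims <- c(0, 0.3, 0.6, 0.7, 0.75, 0.76, 1)
  tiers <- vapply(sims, function(x) {
    if (x > 0.75) "auto" else if (x >= 0.6) "review" else "reject"
  }, character(1))
  expect_identical(tiers, c("reject", "reject", "review", "review",
                            "review", "auto", "auto"))
})

test_that("exact ties resolve to the lexicographically smallest term", {
  # unigram features make "AB" and "BA" identical vectors
  m <- fit_tfidf(c("BA", "AB", "CD"), ngram_range = c(1, 1))
  d <- map_entity("AB", m)
  expect_equal(d$similarity, 1)
  expect_identical(d$best_match, "AB")
  d2 <- map_entity("BAB", m)
  expect_identical(d2$best_match, "AB")
})

test_that("lightly edited variants are recovered in auto/review tiers", {
  cfg <- generator_config(seed = 23)
  dicts <- generate_dictionaries(cfg)
  pairs <- generate_variant_pairs(dicts, n = 200, seed = 23)
  m <- fit_tfidf(dicts$disease)
  res <- do.call(rbind, lapply(pairs$query, map_entity, model = m))
  ok <- res$tier != "reject" & !is.na(res$best_match) &
    res$best_match == pairs$gold
  expect_gte(mean(ok), 0.9)
})

test_that("route_by_type sends each category to its reference corpus", {
  cfg <- generator_config(seed = 29)
  dicts <- generate_dictionaries(cfg)
  models <- list(website = fit_tfidf(c(dicts$disease, dicts$symptom)),
                 terminology = fit_tfidf(dicts$treatment_options))
  ents <- data.frame(
    entity_type = c("disease", "treatment_options", "food"),
    surface = c(dicts$disease[1], dicts$treatment_options[1], "牛奶"),
    stringsAsFactors = FALSE)
  out <- route_by_type(ents, models)
  expect_identical(out$reference, c("website", "terminology", NA))
  expect_identical(out$tier[1:2], c("auto", "auto"))
  # unrouted types pass through verbatim in the reject tier
  expect_identical(out$tier[3], "reject")
  expect_identical(out$canonical[3], "牛奶")
  # canonicalization is idempotent: canonical forms map to themselves
  again <- route_by_type(transform(out[c("entity_type")],
                                   surface = out$canonical), models)
  expect_identical(again$canonical, out$canonical)
  # review queue file is written
  rq <- withr::local_tempfile(fileext = ".tsv")
  invisible(route_by_type(ents, models, review_file = rq))
  expect_true(file.exists(rq))
  # missing reference corpus is a configuration error
  expect_error(route_by_type(ents, models["website"]), "terminology")
})
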