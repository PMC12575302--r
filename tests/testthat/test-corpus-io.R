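test_that("normalize_text applies ordered rules, is idempotent, handles edges", {
  rules <- default_normalization_rules()
  expect_identical(normalize_text("2015年 3月  5日", rules), "2015-03-05")
  expect_identical(normalize_text("", rules), "")
  expect_identical(normalize_text("any text", list()), "any text")
  # idempotence on assorted inputs
  set.seed(5)
  for (raw in c("2020年12月1日查CT", "a  b\t c", "5ml  注射",
                paste(sample(c(letters, " ", "年"), 40, TRUE), collapse = ""))) {
    once <- normalize_text(raw, rules)
    expect_identical(normalize_text(once, rules), once)
  }
  expect_error(normalize_text("x", list(list(pattern = "(", replacement = ""))),
               "malformed")
  expect_error(normalize_text("x", list(list(pattern = "a"))), "malformed")
})

test_that("de-identification rule maps identical identifiers to one code", {
  rule <- make_deid_rule("ID\\d{6}", prefix = "PT")
  out <- normalize_text("ID123456就诊, 陪同ID654321, 复诊ID123456", list(rule))
  expect_identical(out, "PT-0001就诊, 陪同PT-0002, 复诊PT-0001")
})

test_that("parse_ann recovers typed character offsets and validates them", {
  text <- paste0(strrep("甲", 280), "乙丙丁戊己庚辛壬癸子丑", "尾部")
  doc <- parse_ann(text, "T1\tdisease 280 291\t乙丙丁戊己庚辛壬癸子丑")
  expect_identical(doc$spans$span_id, "T1")
  expect_identical(doc$spans$entity_type, "disease")
  expect_identical(doc$spans$start, 280L)
  expect_identical(doc$spans$end, 291L)
  expect_identical(doc$spans$surface, "乙丙丁戊己庚辛壬癸子丑")
  # offsets outside the text name the span
  expect_error(parse_ann("short", "T9\tdisease 2 99\tx"), "T9")
  # surface mismatch: error in strict mode, repaired warning otherwise
  expect_error(parse_ann("abcdef", "T1\tdisease 0 2\txx"), "mismatch")
  expect_warning(d2 <- parse_ann("abcdef", "T1\tdisease 0 2\txx",
                                 strict = FALSE), "mismatch")
  expect_identical(d2$spans$surface, "ab")
  expect_identical(nrow(parse_ann("abc", character())$spans), 0L)
})

test_that("overlapping spans are rejected, or resolved by keep-longest", {
  spans <- data.frame(span_id = c("T1", "T2"),
                      entity_type = c("disease", "symptom"),
                      start = c(0L, 2L), end = c(4L, 5L),
                      surface = c("abcd", "cde"))
  expect_error(annotated_document("d", "abcdef", spans), "T1.*T2")
  doc <- annotated_document("d", "abcdef", spans, overlap = "keep_longest")
  expect_identical(doc$spans$span_id, "T1")
})

test_that("BRAT round-trip reproduces a generated corpus exactly", {
  fx <- small_corpus(n_docs = 100, seed = 7)
  for (doc in fx$docs[1:5]) {
    reparsed <- parse_ann(doc$text, write_ann(doc), doc_id = doc$doc_id)
    expect_identical(reparsed$spans, doc$spans)
    expect_identical(write_ann(reparsed), write_ann(doc))
  }
  dir <- withr::local_tempdir()
  write_brat(fx$docs, dir)
  back <- read_brat(dir)
  expect_length(back, length(fx$docs))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$text, fx$docs[[i]]$text)
    expect_identical(back[[i]]$spans, fx$docs[[i]]$spans)
  }
})

test_that("spans_to_bio labels B on first covered token, I after", {
  doc <- annotated_document("d", "abcdef",
                            data.frame(span_id = "T1",
                                       entity_type = "disease",
                                       start = 2L, end = 5L,
                                       surface = "cde"))
  seqs <- spans_to_bio(doc, sentence_split = NULL)
  expect_length(seqs, 1)
  expect_identical(seqs[[1]]$labels,
                   c("O", "O", "B-disease", "I-disease", "I-disease", "O"))
  # no spans -> all O
  empty <- spans_to_bio(annotated_document("e", "abcd"),
                        sentence_split = NULL)
  expect_identical(empty[[1]]$labels, rep("O", 4))
  # adjacent same-type spans restart with B
  adj <- annotated_document("a", "abcd",
                            data.frame(span_id = c("T1", "T2"),
                                       entity_type = "disease",
                                       start = c(0L, 2L), end = c(2L, 4L),
                                       surface = c("ab", "cd")))
  expect_identical(spans_to_bio(adj, sentence_split = NULL)[[1]]$labels,
                   c("B-disease", "I-disease", "B-disease", "I-disease"))
})

test_that("spans crossing a sentence boundary are an error naming them", {
  doc <- annotated_document("d", "ab。cd",
                            data.frame(span_id = "T1",
                                       entity_type = "disease",
                                       start = 1L, end = 4L,
                                       surface = "b。c"))
  expect_error(spans_to_bio(doc), "T1")
})

test_that("bio_to_spans inverts spans_to_bio; strict mode flags bad input", {
  s <- tag_sequence(chars("abcd"), c("O", "B-disease", "I-disease", "O"))
  sp <- bio_to_spans(s)
  expect_identical(sp$start, 1L)
  expect_identical(sp$end, 3L)
  expect_identical(sp$surface, "bc")
  expect_identical(nrow(bio_to_spans(tag_sequence(chars("ab"), c("O", "O")))),
                   0L)
  expect_error(tag_sequence(chars("ab"), c("O", "I-disease")), "invalid BIO")
  bad <- tag_sequence(chars("ab"), c("O", "I-disease"), validate = FALSE)
  expect_error(bio_to_spans(bad), "position 2")
  repaired <- bio_to_spans(bad, strict = FALSE)
  expect_identical(repaired$entity_type, "disease")
  # round-trip identity over a generated corpus; B-count equals span count
  fx <- small_corpus(n_docs = 100, mentions = 3, seed = 31)
  for (doc in fx$docs) {
    seqs <- spans_to_bio(doc)
    expect_true(all(vapply(seqs, function(s) is_bio_valid(s$labels),
                           logical(1))))
    got <- do.call(rbind, lapply(seqs, bio_to_spans))
    expect_equal(got[c("entity_type", "start", "end", "surface")],
                 doc$spans[c("entity_type", "start", "end", "surface")],
                 ignore_attr = TRUE)
    n_b <- sum(vapply(seqs, function(s) sum(startsWith(s$labels, "B-")),
                      integer(1)))
    expect_identical(n_b, nrow(doc$spans))
  }
})

test_that("BIO TSV round-trips tokens and labels", {
  fx <- small_corpus(n_docs = 10, seed = 17)
  seqs <- corpus_seqs(fx$docs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bio(seqs, path)
  back <- read_bio(path)
  expect_length(back, length(seqs))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$tokens, seqs[[i]]$tokens)
    expect_identical(back[[i]]$labels, seqs[[i]]$labels)
  }
})

test_that("split_dataset partitions exactly with seed determinism", {
  docs <- as.list(letters[1:10])
  parts <- split_dataset(docs, c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(lengths(parts), c(train = 8L, dev = 1L, test = 1L))
  expect_setequal(unlist(parts), unlist(docs))
  expect_identical(split_dataset(docs, c(0.8, 0.1, 0.1), seed = 4), parts)
  other <- split_dataset(docs, c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(lengths(other), lengths(parts))
  expect_false(identical(other, parts))
  expect_identical(split_dataset(list("x"), c(1, 0, 0))$train, list("x"))
  expect_error(split_dataset(list("x"), c(0.5, 0.3, 0.2)), "fewer")
  expect_error(split_dataset(docs, c(0.5, 0.4)), "sum to 1")
  # uneven n: sizes still exhaustive and disjoint
  p7 <- split_dataset(as.list(1:7), c(0.8, 0.1, 0.1), seed = 2)
  expect_identical(sum(lengths(p7)), 7L)
  expect_identical(anyDuplicated(unlist(p7)), 0L)
})
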