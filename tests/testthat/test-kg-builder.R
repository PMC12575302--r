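one_patient_doc <- function() {
  # two diseases, three symptoms embedded in carrier text
  text <- "xxDDDyySSyAAyyBByCCCy"
  spans <- data.frame(
    span_id = paste0("T", 1:5),
    entity_type = c("disease", "symptom", "disease", "symptom", "symptom"),
    start = c(2L, 7L, 10L, 14L, 17L),
    end = c(5L, 9L, 12L, 16L, 20L),
    surface = c("DDD", "SS", "AA", "BB", "CCC"))
  annotated_document("p1", text, spans)
}

test_that("validate_triple enforces relation domain/range and self-loops", {
  sch <- default_schema()
  expect_length(sch$entity_types, 11)
  expect_identical(nrow(sch$relations), 18L)
  ok <- validate_triple(sch, list(subject_type = "disease", subject = "d",
                                  relation = "has_symptom",
                                  object_type = "symptom", object = "s"))
  expect_true(ok)
  rev <- validate_triple(sch, list(subject_type = "symptom", subject = "s",
                                   relation = "has_symptom",
                                   object_type = "disease", object = "d"))
  expect_false(isTRUE(rev))
  expect_match(attr(rev, "reason"), "domain")
  # self-typed disease-complication relation passes
  acc <- validate_triple(sch, list(subject_type = "disease", subject = "d1",
                                   relation = "accompany_with",
                                   object_type = "disease", object = "d2"))
  expect_true(acc)
  loop <- validate_triple(sch, list(subject_type = "disease", subject = "d1",
                                    relation = "accompany_with",
                                    object_type = "disease", object = "d1"))
  expect_false(isTRUE(loop))
  expect_error(validate_triple(sch, list(subject_type = "disease",
                                         subject = "d", relation = "cures",
                                         object_type = "drug", object = "x")),
               "unknown relation")
  expect_error(kg_schema(c("a", "b"),
                         data.frame(relation = "r", domain = "a",
                                    range = "zzz")), "unregistered")
})

test_that("assemble_kg builds patient-centric triples with exact counts", {
  doc <- one_patient_doc()
  # direct mode: 1 patient + 2 diseases + 3 symptoms; one link each
  st <- assemble_kg(list(doc), proxy = FALSE)
  expect_identical(nrow(st$entities), 6L)
  expect_identical(nrow(st$triples), 5L)
  expect_identical(as.integer(st$counts$entities[c("patient", "disease",
                                                   "symptom")]),
                   c(1L, 2L, 3L))
  expect_identical(as.integer(st$counts$relations[["rels_disease"]]), 2L)
  expect_identical(as.integer(st$counts$relations[["rels_symptom"]]), 3L)
  # proxy mode materializes one hub per category
  stp <- assemble_kg(list(doc), proxy = TRUE)
  expect_identical(nrow(stp$entities), 8L)            # + 2 hub nodes
  expect_identical(nrow(stp$triples), 7L)             # 2 hub links + 5
  expect_identical(as.integer(stp$counts$relations[["belongs_to"]]), 5L)
  # empty input and idempotent deduplication
  expect_identical(nrow(assemble_kg(list())$triples), 0L)
  expect_identical(assemble_kg(list(doc, doc), proxy = FALSE)$triples,
                   st$triples)
  # referential integrity: every endpoint is a registered entity
  keys <- paste(st$entities$entity_type, st$entities$name)
  expect_true(all(paste(st$triples$subject_type, st$triples$subject)
                  %in% keys))
  expect_true(all(paste(st$triples$object_type, st$triples$object)
                  %in% keys))
})

test_that("schema-invalid reference triples are dropped and reported", {
  bad <- data.frame(subject_type = "symptom", subject = "s",
                    relation = "has_symptom", object_type = "disease",
                    object = "d", stringsAsFactors = FALSE)
  good <- data.frame(subject_type = "disease", subject = "d",
                     relation = "has_symptom", object_type = "symptom",
                     object = "s", stringsAsFactors = FALSE)
  st <- assemble_kg(list(), rbind(bad, good))
  expect_identical(nrow(st$triples), 1L)
  rej <- attr(st, "rejected")
  expect_identical(nrow(rej), 1L)
  expect_match(rej$reason, "domain")
})

test_that("CSV export round-trips stores, including awkward names", {
  doc <- one_patient_doc()
  ext <- data.frame(subject_type = "disease", subject = "DDD",
                    relation = "has_symptom", object_type = "symptom",
                    object = 'me, the "odd" one', stringsAsFactors = FALSE)
  st <- assemble_kg(list(doc), ext, proxy = FALSE,
                    patient_attrs = data.frame(name = "p1", nation = "Han",
                                               age = 63, sex = "F"))
  dir <- withr::local_tempdir()
  export_kg_csv(st, dir)
  expect_true(file.exists(file.path(dir, "nodes_patient.csv")))
  rel <- utils::read.csv(file.path(dir, "relationships.csv"),
                         check.names = FALSE)
  expect_identical(nrow(rel), 6L)
  expect_true(all(c(":START_ID", ":TYPE", ":END_ID") %in% names(rel)))
  back <- import_kg_csv(dir)
  expect_identical(back$triples, st$triples)
  expect_identical(back$entities$name, st$entities$name)
  expect_identical(back$counts, st$counts)
  # patient attributes survive
  pat <- utils::read.csv(file.path(dir, "nodes_patient.csv"),
                         check.names = FALSE)
  expect_identical(pat$nation, "Han")
})

test_that("Cypher export matches the golden form and round-trips", {
  doc <- annotated_document(
    "p1", "xxHCCyy",
    data.frame(span_id = "T1", entity_type = "disease", start = 2L,
               end = 5L, surface = "HCC"))
  st <- assemble_kg(list(doc), proxy = FALSE)
  f <- withr::local_tempfile(fileext = ".cypher")
  export_kg_cypher(st, f)
  expect_identical(
    readLines(f),
    c("MERGE (:disease {id: 'disease/HCC', name: 'HCC'});",
      "MERGE (:patient {id: 'patient/p1', name: 'p1'});",
      paste0("MATCH (a {id: 'patient/p1'}), (b {id: 'disease/HCC'}) ",
             "MERGE (a)-[:rels_disease {provenance: 'p1'}]->(b);")))
  back <- import_kg_cypher(f)
  expect_identical(back$triples, st$triples)
  expect_identical(back$entities$name, st$entities$name)
  # quoted characters survive the round-trip
  ext <- data.frame(subject_type = "disease", subject = "HCC",
                    relation = "has_symptom", object_type = "symptom",
                    object = "it's 'odd'", stringsAsFactors = FALSE)
  st2 <- assemble_kg(list(doc), ext, proxy = FALSE)
  export_kg_cypher(st2, f)
  expect_identical(import_kg_cypher(f)$triples, st2$triples)
})

test_that("multi-hop retrieval follows the exact relation path", {
  # patient -> disease -> complication on a 5-node toy graph
  doc <- annotated_document(
    "p9", "aaDDbb",
    data.frame(span_id = "T1", entity_type = "disease", start = 2L,
               end = 4L, surface = "DD"))
  ext <- data.frame(
    subject_type = c("disease", "disease", "disease"),
    subject = c("DD", "DD", "XX"),
    relation = c("accompany_with", "has_symptom", "accompany_with"),
    object_type = c("disease", "symptom", "disease"),
    object = c("COMP", "SYM", "OTHER"), stringsAsFactors = FALSE)
  st <- assemble_kg(list(doc), ext, proxy = FALSE)
  hits <- query_multihop(st, "patient", "p9",
                         c("rels_disease", "accompany_with"))
  expect_identical(hits$name, "COMP")
  # empty path returns the start entity itself
  self <- query_multihop(st, "patient", "p9", character())
  expect_identical(self$name, "p9")
  # a relation absent from the graph empties the frontier
  none <- query_multihop(st, "patient", "p9",
                         c("rels_disease", "recommand_drug"))
  expect_identical(nrow(none), 0L)
  expect_warning(miss <- query_multihop(st, "patient", "ghost",
                                        c("rels_disease")), "not in store")
  expect_identical(nrow(miss), 0L)
  expect_error(query_multihop(st, "patient", "p9", "fly_to"),
               "unregistered")
})

test_that("multi-hop agrees with an adjacency-matrix oracle on random graphs", {
  sch <- default_schema()
  rels <- c("rels_disease", "accompany_with", "has_symptom", "belongs_to")
  set.seed(31)
  for (rep in 1:10) {
    diseases <- paste0("d", 1:5)
    ext <- unique(data.frame(
      subject_type = "disease",
      subject = sample(diseases, 12, TRUE),
      relation = sample(c("accompany_with", "has_symptom"), 12, TRUE),
      object_type = NA, object = NA, stringsAsFactors = FALSE))
    ext$object_type <- ifelse(ext$relation == "has_symptom", "symptom",
                              "disease")
    ext$object <- ifelse(ext$relation == "has_symptom",
                         paste0("s", sample(1:4, nrow(ext), TRUE)),
                         sample(diseases, nrow(ext), TRUE))
    ext <- ext[!(ext$relation == "accompany_with" &
                   ext$subject == ext$object), ]
    st <- assemble_kg(list(), ext, sch)
    path <- sample(rels, sample(1:3, 1), TRUE)
    start <- c("disease", sample(diseases, 1))
    if (!any(st$entities$entity_type == start[1] &
               st$entities$name == start[2])) next
    got <- query_multihop(st, start[1], start[2], path)
    expect_identical(paste(got$entity_type, got$name, sep = "/"),
                     multihop_oracle(st, start[1], start[2], path))
  }
})
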