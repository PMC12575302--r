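# Knowledge-graph schema, triple assembly, statistics, bulk-import
# CSV / Cypher export, and multi-hop retrieval.
#
# Node identity is (entity_type, canonical name); patients are keyed by
# their generated patient ID. Relations carry a declared domain and range
# ("*" = any registered type), read from a schema config file so
# corrections need no code change.

#' Knowledge-graph schema
#'
#' Registers entity types, relations with domain/range, and per-type
#' attribute keys. [default_schema()] loads the shipped conceptual layer:
#' 11 clinical entity types (patient, examination, symptom, disease, past
#' history, operation recording, treatment options, physical examination,
#' food, drug, department), an 18-relation inventory (patient-record
#' relations `rels_*`, website relations such as `has_symptom`,
#' `recommand_drug`, `accompany_with`, and `belongs_to` with wildcard
#' endpoints), and patient attributes (`nation`, `age`, `sex`).
#'
#' @param entity_types Character vector of registered types.
#' @param relations data.frame with columns `relation`, `domain`, `range`
#'   (`"*"` matches any registered type); relation names must be unique.
#' @param attributes Named list: per-type attribute keys.
#' @return Object of class `kg_schema`.
#' @export
kg_schema <- function(entity_types, relations, attributes = list()) {
  stopifnot(is.character(entity_types),
            all(c("relation", "domain", "range") %in% names(relations)))
  if (anyDuplicated(relations$relation)) {
    stop_emrkg("duplicate relation names in schema")
  }
  ok <- function(x) x == "*" | x %in% entity_types
  bad <- !(ok(relations$domain) & ok(relations$range))
  if (any(bad)) {
    stop_emrkg("relation(s) with unregistered domain/range: %s",
               paste(relations$relation[bad], collapse = ", "))
  }
  structure(list(entity_types = entity_types,
                 relations = relations[c("relation", "domain", "range")],
                 attributes = attributes),
            class = "kg_schema")
}

#' @rdname kg_schema
#' @export
default_schema <- function() {
  ets <- readLines(system.file("extdata", "kg_entity_types.txt",
                               package = "emrkg"), encoding = "UTF-8")
  rels <- utils::read.delim(system.file("extdata", "kg_relations.tsv",
                                        package = "emrkg"),
                            stringsAsFactors = FALSE)
  kg_schema(ets, rels,
            attributes = list(patient = c("nation", "age", "sex")))
}

# relation connecting a patient record to each EMR entity category
patient_relation_map <- function() {
  c(examination = "rels_check", symptom = "rels_symptom",
    disease = "rels_disease", past_history = "rels_condition",
    operation_recording = "rels_operation",
    treatment_options = "rels_treatment",
    physical_examination = "rels_body")
}

#' Validate a triple against a schema
#'
#' A triple passes iff its relation is registered and the subject / object
#' entity types satisfy the relation's declared domain / range; self-loops
#' (subject equal to object under a self-typed relation) are rejected
#' unless whitelisted.
#'
#' @param schema A [kg_schema()].
#' @param triple List or one-row data.frame with `subject_type`,
#'   `subject`, `relation`, `object_type`, `object`.
#' @param allow_self Relations for which subject == object is permitted.
#' @return `TRUE`, or `FALSE` with the violated constraint in
#'   `attr(, "reason")`. An unknown relation is an error.
#' @export
validate_triple <- function(schema, triple, allow_self = character()) {
  stopifnot(inherits(schema, "kg_schema"))
  row <- schema$relations[schema$relations$relation == triple$relation, ]
  if (!nrow(row)) stop_emrkg("unknown relation: %s", triple$relation)
  fail <- function(reason) structure(FALSE, reason = reason)
  if (!triple$subject_type %in% schema$entity_types) {
    return(fail(sprintf("unregistered subject type %s", triple$subject_type)))
  }
  if (!triple$object_type %in% schema$entity_types) {
    return(fail(sprintf("unregistered object type %s", triple$object_type)))
  }
  if (row$domain != "*" && triple$subject_type != row$domain) {
    return(fail(sprintf("domain violation: %s expects subject %s, got %s",
                        triple$relation, row$domain, triple$subject_type)))
  }
  if (row$range != "*" && triple$object_type != row$range) {
    return(fail(sprintf("range violation: %s expects object %s, got %s",
                        triple$relation, row$range, triple$object_type)))
  }
  if (triple$subject_type == triple$object_type &&
      identical(triple$subject, triple$object) &&
      !triple$relation %in% allow_self) {
    return(fail(sprintf("self-loop under %s", triple$relation)))
  }
  TRUE
}

empty_triples <- function() {
  data.frame(subject_type = character(), subject = character(),
             relation = character(), object_type = character(),
             object = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

new_store <- function(schema, entities, triples) {
  entities <- unique(entities)
  entities <- entities[order(entities$entity_type, entities$name), ,
                       drop = FALSE]
  rownames(entities) <- NULL
  triples <- unique(triples)
  triples <- triples[order(triples$relation, triples$subject_type,
                           triples$subject, triples$object_type,
                           triples$object), , drop = FALSE]
  rownames(triples) <- NULL
  structure(list(schema = schema, entities = entities, triples = triples,
                 counts = list(
                   entities = table(factor(entities$entity_type,
                                           levels = schema$entity_types)),
                   relations = table(factor(triples$relation,
                                            levels = schema$relations$relation)))),
            class = "triple_store")
}

#' @export
print.triple_store <- function(x, ...) {
  cat(sprintf("<triple_store: %d entities (%d types), %d triples (%d relations)>\n",
              nrow(x$entities), sum(x$counts$entities > 0),
              nrow(x$triples), sum(x$counts$relations > 0)))
  invisible(x)
}

#' Assemble a triple store from annotated documents
#'
#' Builds patient-centric triples from EMR documents (one patient node per
#' document, keyed by its patient/document ID, linked to each entity
#' mention through the patient-record relation of its category — e.g.
#' `rels_disease` for diseases) plus imported reference relations (e.g.
#' website disease–symptom links). With `proxy = TRUE` (default), a
#' per-patient category hub node is materialized between the patient and
#' its specific entities (`patient -rels_x-> hub -belongs_to-> entity`);
#' with `proxy = FALSE` the patient links directly. Entity surfaces are
#' expected to be canonicalized (see [route_by_type()]) before assembly.
#'
#' Duplicate triples are collapsed, so assembling the same corpus twice
#' yields an identical store. Triples failing schema validation are
#' dropped and reported in `attr(, "rejected")`.
#'
#' @param docs List of [annotated_document()] objects (may be empty).
#' @param external_relations Optional data.frame of reference triples
#'   (`subject_type`, `subject`, `relation`, `object_type`, `object`,
#'   optional `provenance`).
#' @param schema A [kg_schema()].
#' @param proxy Materialize per-patient category hub nodes (default
#'   `TRUE`).
#' @param patient_attrs Optional data.frame of patient attributes keyed by
#'   a `name` column (plus the schema's patient attribute columns).
#' @param allow_self Passed to [validate_triple()].
#' @return Object of class `triple_store` with `entities`, `triples`, and
#'   recomputed per-type / per-relation `counts`.
#' @export
assemble_kg <- function(docs = list(), external_relations = NULL,
                        schema = default_schema(), proxy = TRUE,
                        patient_attrs = NULL, allow_self = character()) {
  prm <- patient_relation_map()
  ents <- list(); trps <- list()
  add_ent <- function(type, name) {
    ents[[length(ents) + 1L]] <<- data.frame(entity_type = type,
                                             name = name,
                                             stringsAsFactors = FALSE)
  }
  add_trp <- function(st, s, r, ot, o, prov) {
    trps[[length(trps) + 1L]] <<- data.frame(
      subject_type = st, subject = s, relation = r, object_type = ot,
      object = o, provenance = prov, stringsAsFactors = FALSE)
  }
  for (doc in docs) {
    pid <- doc$doc_id
    add_ent("patient", pid)
    if (!nrow(doc$spans)) next
    for (cat in unique(doc$spans$entity_type)) {
      rel <- prm[[cat]]
      if (is.null(rel)) next # non-EMR category in a document: skip
      names_cat <- unique(doc$spans$surface[doc$spans$entity_type == cat])
      if (proxy) {
        hub <- sprintf("%s_%s", pid, cat)
        add_ent(cat, hub)
        add_trp("patient", pid, rel, cat, hub, pid)
        for (nm in names_cat) {
          add_ent(cat, nm)
          add_trp(cat, hub, "belongs_to", cat, nm, pid)
        }
      } else {
        for (nm in names_cat) {
          add_ent(cat, nm)
          add_trp("patient", pid, rel, cat, nm, pid)
        }
      }
    }
  }
  if (!is.null(external_relations) && nrow(external_relations)) {
    er <- external_relations
    if (is.null(er$provenance)) er$provenance <- "reference"
    for (i in seq_len(nrow(er))) {
      add_ent(er$subject_type[i], er$subject[i])
      add_ent(er$object_type[i], er$object[i])
      add_trp(er$subject_type[i], er$subject[i], er$relation[i],
              er$object_type[i], er$object[i], er$provenance[i])
    }
  }
  entities <- if (length(ents)) do.call(rbind, ents) else
    data.frame(entity_type = character(), name = character(),
               stringsAsFactors = FALSE)
  triples <- if (length(trps)) do.call(rbind, trps) else empty_triples()
  # schema validation: collect failures, drop offending triples
  rejected <- empty_triples(); rejected$reason <- character()
  if (nrow(triples)) {
    keep <- logical(nrow(triples))
    reasons <- character(nrow(triples))
    for (i in seq_len(nrow(triples))) {
      v <- validate_triple(schema, triples[i, ], allow_self = allow_self)
      keep[i] <- isTRUE(v)
      if (!keep[i]) reasons[i] <- attr(v, "reason")
    }
    if (any(!keep)) {
      rejected <- cbind(triples[!keep, , drop = FALSE],
                        reason = reasons[!keep])
      rownames(rejected) <- NULL
    }
    triples <- triples[keep, , drop = FALSE]
  }
  # entity attributes (patients only by default)
  for (attr_type in names(schema$attributes)) {
    for (key in schema$attributes[[attr_type]]) {
      entities[[key]] <- rep(NA, nrow(entities))
    }
  }
  if (!is.null(patient_attrs) && nrow(patient_attrs)) {
    idx <- match(entities$name, patient_attrs$name)
    hit <- entities$entity_type == "patient" & !is.na(idx)
    for (key in setdiff(names(patient_attrs), "name")) {
      entities[[key]][hit] <- patient_attrs[[key]][idx[hit]]
    }
  }
  store <- new_store(schema, entities, triples)
  attr(store, "rejected") <- rejected
  store
}

node_id <- function(type, name) paste(type, name, sep = "/")

#' Export a triple store as bulk-import CSVs
#'
#' Writes one node CSV per entity type (`nodes_<type>.csv` with headers
#' `id:ID`, `name`, `type:LABEL` plus any attribute columns) and a single
#' `relationships.csv` (`:START_ID`, `:TYPE`, `:END_ID`, `provenance`),
#' following the graph-database bulk-import header convention. Names
#' containing quotes or commas survive CSV quoting; [import_kg_csv()]
#' round-trips the store exactly.
#'
#' @param store A `triple_store`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
export_kg_csv <- function(store, out_dir) {
  stopifnot(inherits(store, "triple_store"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tt in unique(store$entities$entity_type)) {
    e <- store$entities[store$entities$entity_type == tt, , drop = FALSE]
    df <- data.frame(`id:ID` = node_id(e$entity_type, e$name),
                     name = e$name, `type:LABEL` = e$entity_type,
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (key in setdiff(names(e), c("entity_type", "name"))) {
      if (any(!is.na(e[[key]]))) df[[key]] <- e[[key]]
    }
    utils::write.csv(df, file.path(out_dir, sprintf("nodes_%s.csv", tt)),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  tr <- store$triples
  rel <- data.frame(`:START_ID` = node_id(tr$subject_type, tr$subject),
                    `:TYPE` = tr$relation,
                    `:END_ID` = node_id(tr$object_type, tr$object),
                    provenance = tr$provenance,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(rel, file.path(out_dir, "relationships.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out_dir)
}

#' Re-import a bulk-import CSV directory
#'
#' Inverse of [export_kg_csv()]: reads the node and relationship CSVs back
#' into a `triple_store` equal to the exported one (entities, triples and
#' counts).
#'
#' @param dir Directory written by [export_kg_csv()].
#' @param schema A [kg_schema()].
#' @return A `triple_store`.
#' @export
import_kg_csv <- function(dir, schema = default_schema()) {
  node_files <- list.files(dir, pattern = "^nodes_.*\\.csv$",
                           full.names = TRUE)
  ents <- lapply(node_files, function(f) {
    df <- utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = "character")
    out <- data.frame(entity_type = df[["type:LABEL"]], name = df$name,
                      stringsAsFactors = FALSE)
    for (key in setdiff(names(df), c("id:ID", "name", "type:LABEL"))) {
      out[[key]] <- df[[key]]
    }
    out
  })
  cols <- unique(unlist(lapply(ents, names)))
  ents <- lapply(ents, function(e) {
    for (key in setdiff(cols, names(e))) e[[key]] <- NA
    e[cols]
  })
  entities <- do.call(rbind, ents)
  for (attr_type in names(schema$attributes)) {
    for (key in schema$attributes[[attr_type]]) {
      if (is.null(entities[[key]])) {
        entities[[key]] <- rep(NA, nrow(entities))
      }
    }
  }
  rel <- utils::read.csv(file.path(dir, "relationships.csv"),
                         check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", colClasses = "character")
  split_id <- function(x) {
    pos <- regexpr("/", x, fixed = TRUE)
    list(type = substr(x, 1, pos - 1), name = substring(x, pos + 1))
  }
  s <- split_id(rel[[":START_ID"]]); o <- split_id(rel[[":END_ID"]])
  triples <- data.frame(subject_type = s$type, subject = s$name,
                        relation = rel[[":TYPE"]],
                        object_type = o$type, object = o$name,
                        provenance = rel$provenance,
                        stringsAsFactors = FALSE)
  new_store(schema, entities, triples)
}

cypher_quote <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("'", "\\'", x, fixed = TRUE)
  sprintf("'%s'", x)
}

#' Export a triple store as Cypher MERGE statements
#'
#' Emits one `MERGE` per node and per relationship, reproducing the same
#' graph on any Cypher-speaking database; no server is required to write
#' or parse the file. [import_kg_cypher()] round-trips the store.
#'
#' @param store A `triple_store`.
#' @param out_file Output path.
#' @return `out_file`, invisibly.
#' @export
export_kg_cypher <- function(store, out_file) {
  stopifnot(inherits(store, "triple_store"))
  e <- store$entities
  node_lines <- sprintf("MERGE (:%s {id: %s, name: %s});", e$entity_type,
                        cypher_quote(node_id(e$entity_type, e$name)),
                        cypher_quote(e$name))
  tr <- store$triples
  rel_lines <- if (nrow(tr)) {
    sprintf(paste0("MATCH (a {id: %s}), (b {id: %s}) ",
                   "MERGE (a)-[:%s {provenance: %s}]->(b);"),
            cypher_quote(node_id(tr$subject_type, tr$subject)),
            cypher_quote(node_id(tr$object_type, tr$object)),
            tr$relation, cypher_quote(tr$provenance))
  } else character()
  writeLines(c(node_lines, rel_lines), out_file, useBytes = FALSE)
  invisible(out_file)
}

#' @rdname export_kg_cypher
#' @param in_file Cypher file written by [export_kg_cypher()].
#' @param schema A [kg_schema()].
#' @export
import_kg_cypher <- function(in_file, schema = default_schema()) {
  lines <- readLines(in_file, encoding = "UTF-8")
  unq <- function(x) gsub("\\\\(.)", "\\1", x)
  node_pat <- "^MERGE \\(:([^ ]+) \\{id: '((?:[^'\\\\]|\\\\.)*)', name: '((?:[^'\\\\]|\\\\.)*)'\\}\\);$"
  rel_pat <- paste0("^MATCH \\(a \\{id: '((?:[^'\\\\]|\\\\.)*)'\\}\\), ",
                    "\\(b \\{id: '((?:[^'\\\\]|\\\\.)*)'\\}\\) ",
                    "MERGE \\(a\\)-\\[:([^ ]+) \\{provenance: ",
                    "'((?:[^'\\\\]|\\\\.)*)'\\}\\]->\\(b\\);$")
  is_node <- grepl(node_pat, lines, perl = TRUE)
  is_rel <- grepl(rel_pat, lines, perl = TRUE)
  ents <- if (any(is_node)) {
    m <- regmatches(lines[is_node], regexec(node_pat, lines[is_node],
                                            perl = TRUE))
    data.frame(entity_type = vapply(m, `[`, character(1), 2),
               name = unq(vapply(m, `[`, character(1), 4)),
               stringsAsFactors = FALSE)
  } else data.frame(entity_type = character(), name = character(),
                    stringsAsFactors = FALSE)
  for (attr_type in names(schema$attributes)) {
    for (key in schema$attributes[[attr_type]]) {
      ents[[key]] <- rep(NA, nrow(ents))
    }
  }
  triples <- if (any(is_rel)) {
    m <- regmatches(lines[is_rel], regexec(rel_pat, lines[is_rel],
                                           perl = TRUE))
    sid <- unq(vapply(m, `[`, character(1), 2))
    oid <- unq(vapply(m, `[`, character(1), 3))
    pos_s <- regexpr("/", sid, fixed = TRUE)
    pos_o <- regexpr("/", oid, fixed = TRUE)
    data.frame(subject_type = substr(sid, 1, pos_s - 1),
               subject = substring(sid, pos_s + 1),
               relation = vapply(m, `[`, character(1), 4),
               object_type = substr(oid, 1, pos_o - 1),
               object = substring(oid, pos_o + 1),
               provenance = unq(vapply(m, `[`, character(1), 5)),
               stringsAsFactors = FALSE)
  } else empty_triples()
  new_store(schema, ents, triples)
}

#' Multi-hop retrieval along a fixed relation path
#'
#' Starting from one entity, follows the exact relation sequence (e.g.
#' `rels_disease` then `accompany_with` to go patient -> disease ->
#' complication) and returns every entity reachable at the end of the
#' path, in deterministic lexicographic order. An empty path returns the
#' start entity; an unknown start yields an empty result with a warning.
#'
#' @param store A `triple_store`.
#' @param start_type,start_name The start entity.
#' @param relation_path Character vector of relation names, applied in
#'   order; each must be registered in the store's schema.
#' @return data.frame (`entity_type`, `name`) of reachable entities.
#' @export
query_multihop <- function(store, start_type, start_name, relation_path) {
  stopifnot(inherits(store, "triple_store"))
  bad <- setdiff(relation_path, store$schema$relations$relation)
  if (length(bad)) {
    stop_emrkg("unregistered relation(s) in path: %s",
               paste(bad, collapse = ", "))
  }
  known <- any(store$entities$entity_type == start_type &
                 store$entities$name == start_name)
  if (!known) {
    warning(sprintf("start entity %s/%s not in store", start_type,
                    start_name), call. = FALSE)
    return(data.frame(entity_type = character(), name = character(),
                      stringsAsFactors = FALSE))
  }
  frontier <- data.frame(entity_type = start_type, name = start_name,
                         stringsAsFactors = FALSE)
  for (rel in relation_path) {
    tr <- store$triples[store$triples$relation == rel, , drop = FALSE]
    hit <- paste(tr$subject_type, tr$subject, sep = "/") %in%
      paste(frontier$entity_type, frontier$name, sep = "/")
    frontier <- unique(data.frame(entity_type = tr$object_type[hit],
                                  name = tr$object[hit],
                                  stringsAsFactors = FALSE))
    if (!nrow(frontier)) break
  }
  frontier <- frontier[order(frontier$entity_type, frontier$name), ,
                       drop = FALSE]
  rownames(frontier) <- NULL
  frontier
}
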