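# Corpus I/O: BRAT standoff annotations, BIO corpora, text normalization,
# span <-> label conversion, and dataset splitting.
#
# Offsets are 0-based, end-exclusive CHARACTER offsets throughout (BRAT
# convention), so a record "T1  disease 280 291  x" covers characters
# 281..291 in R's 1-based substring terms.

#' Construct an annotated document
#'
#' Bundles a clinical note's text with its typed entity spans. Spans are
#' validated against the text (offsets in range, surface form equal to the
#' covered substring), sorted by start offset, and checked for overlap.
#'
#' @param doc_id Document identifier.
#' @param text Document text (single string, UTF-8).
#' @param spans A data.frame with columns `span_id`, `entity_type`,
#'   `start`, `end`, `surface`. Offsets are 0-based, end-exclusive
#'   character positions. May have zero rows.
#' @param overlap How to handle overlapping spans: `"error"` (default)
#'   rejects the document naming both spans; `"keep_longest"` drops the
#'   shorter of each overlapping pair.
#' @param strict If `TRUE` (default) a surface/text mismatch is an error;
#'   otherwise a warning, and the surface is rewritten from the text.
#' @return An object of class `annotated_document`: a list with elements
#'   `doc_id`, `text`, `spans`.
#' @seealso [parse_ann()], [spans_to_bio()]
#' @export
annotated_document <- function(doc_id, text, spans = empty_spans(),
                               overlap = c("error", "keep_longest"),
                               strict = TRUE) {
  overlap <- match.arg(overlap)
  stopifnot(is.character(doc_id), length(doc_id) == 1,
            is.character(text), length(text) == 1, is.data.frame(spans))
  spans <- as.data.frame(spans, stringsAsFactors = FALSE)
  need <- c("span_id", "entity_type", "start", "end", "surface")
  if (!all(need %in% names(spans))) {
    stop_emrkg("spans must have columns %s", paste(need, collapse = ", "))
  }
  spans <- spans[need]
  n_text <- nchar(text)
  if (nrow(spans)) {
    spans$start <- as.integer(spans$start)
    spans$end <- as.integer(spans$end)
    bad <- spans$start < 0 | spans$end > n_text | spans$start >= spans$end
    if (any(bad)) {
      stop_emrkg("span(s) %s outside text [0, %d) or empty",
                 paste(spans$span_id[bad], collapse = ", "), n_text)
    }
    covered <- substr0(text, spans$start, spans$end)
    mism <- covered != spans$surface
    if (any(mism)) {
      msg <- sprintf(
        "surface mismatch for %s: annotation %s vs text %s",
        spans$span_id[which(mism)[1]],
        dQuote(spans$surface[which(mism)[1]]),
        dQuote(covered[which(mism)[1]]))
      if (strict) stop_emrkg("%s", msg)
      warning(msg, call. = FALSE)
      spans$surface[mism] <- covered[mism]
    }
    spans <- spans[order(spans$start, spans$end), , drop = FALSE]
    rownames(spans) <- NULL
    spans <- resolve_overlaps(spans, overlap, doc_id)
  }
  structure(list(doc_id = doc_id, text = text, spans = spans),
            class = "annotated_document")
}

empty_spans <- function() {
  data.frame(span_id = character(), entity_type = character(),
             start = integer(), end = integer(), surface = character(),
             stringsAsFactors = FALSE)
}

resolve_overlaps <- function(spans, overlap, doc_id) {
  repeat {
    if (nrow(spans) < 2) return(spans)
    ov <- which(spans$start[-1] < spans$end[-nrow(spans)])
    if (!length(ov)) return(spans)
    i <- ov[1]
    if (overlap == "error") {
      stop_emrkg("overlapping spans in %s: %s [%d,%d) and %s [%d,%d)",
                 doc_id, spans$span_id[i], spans$start[i], spans$end[i],
                 spans$span_id[i + 1], spans$start[i + 1], spans$end[i + 1])
    }
    len <- spans$end - spans$start
    drop <- if (len[i] >= len[i + 1]) i + 1 else i
    spans <- spans[-drop, , drop = FALSE]
    rownames(spans) <- NULL
  }
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document %s: %d chars, %d spans>\n",
              x$doc_id, nchar(x$text), nrow(x$spans)))
  invisible(x)
}

#' Normalize clinical text with an ordered rule list
#'
#' Applies deterministic pattern -> replacement rules in order. A rule is a
#' list with elements `pattern` (a regular expression) and `replacement`
#' (either a replacement string for [gsub()] or a function receiving the
#' regmatches capture groups of one match and returning its replacement).
#' Typical uses: unifying date/time formats, standardizing measurement
#' units, collapsing redundant whitespace, and rule-based de-identification.
#'
#' Applying the same rule list twice yields the same result for the shipped
#' default rules (idempotence), because each rule's output no longer
#' matches its pattern.
#'
#' @param raw Input text (character scalar).
#' @param rules List of rules, applied in order. See
#'   [default_normalization_rules()].
#' @return Normalized text.
#' @examples
#' normalize_text("2015年 3月  5日", default_normalization_rules())
#' @export
normalize_text <- function(raw, rules = default_normalization_rules()) {
  stopifnot(is.character(raw), length(raw) == 1)
  out <- raw
  for (rule in rules) {
    if (!is.list(rule) || is.null(rule$pattern) ||
        is.null(rule$replacement)) {
      stop_emrkg("malformed normalization rule: need pattern and replacement")
    }
    ok <- tryCatch({suppressWarnings(grepl(rule$pattern, "", perl = TRUE)); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop_emrkg("malformed rule pattern: %s", rule$pattern)
    if (is.function(rule$replacement)) {
      m <- gregexpr(rule$pattern, out, perl = TRUE)
      hits <- regmatches(out, m)[[1]]
      if (length(hits)) {
        groups <- regmatches(out, regexec(rule$pattern, out, perl = TRUE))
        # replace one match at a time so capture groups are per-match
        repl <- vapply(hits, function(h) {
          g <- regmatches(h, regexec(rule$pattern, h, perl = TRUE))[[1]]
          rule$replacement(g)
        }, character(1))
        regmatches(out, m) <- list(repl)
      }
    } else {
      out <- gsub(rule$pattern, rule$replacement, out, perl = TRUE)
    }
  }
  out
}

#' Default text-normalization rules
#'
#' Whitespace collapse, CJK date unification to ISO `YYYY-MM-DD`, and a
#' unit standardization example (`ML`/`ml` -> `mL`). Extend or reorder
#' freely; rules apply in list order.
#'
#' @return A list of rules consumable by [normalize_text()].
#' @export
default_normalization_rules <- function() {
  list(
    list(pattern = "[ \t]+", replacement = " "),
    list(pattern = "(\\d{4})年\\s*(\\d{1,2})月\\s*(\\d{1,2})日",
         replacement = function(g) {
           sprintf("%s-%02d-%02d", g[2], as.integer(g[3]), as.integer(g[4]))
         }),
    list(pattern = "(?<=\\d)(ML|ml)\\b", replacement = "mL")
  )
}

#' Build a de-identification rule
#'
#' Maps every match of `pattern` (e.g. a name or ID-number pattern) to a
#' generated patient code `prefix-0001`, `prefix-0002`, ... Identical
#' surface forms receive the same code, preserving traceability without
#' the identifier itself. This is rule-based replacement only, not a PHI
#' detection model.
#'
#' @param pattern Regular expression matching the identifier.
#' @param prefix Code prefix, default `"PT"`.
#' @return A rule for [normalize_text()].
#' @export
make_deid_rule <- function(pattern, prefix = "PT") {
  seen <- new.env(parent = emptyenv())
  list(pattern = pattern, replacement = function(g) {
    key <- g[1]
    if (is.null(seen[[key]])) {
      seen[[key]] <- sprintf("%s-%04d", prefix, length(ls(seen)) + 1L)
    }
    seen[[key]]
  })
}

#' Parse BRAT standoff entity annotations
#'
#' Parses the entity ("T") lines of a BRAT `.ann` file against the document
#' text. Each line has the form `<id>\tab<type> <start> <end>\tab<surface>`
#' with 0-based, end-exclusive character offsets; e.g. a record with id
#' `T1`, type `disease`, offsets 280 and 291 covers the 11 characters at
#' positions 280..290.
#'
#' @param text Document text the offsets refer to.
#' @param ann_lines Character vector of annotation lines; blank lines and
#'   non-entity lines (ids not starting with "T") are ignored.
#' @param doc_id Identifier for the resulting document.
#' @param strict Passed to [annotated_document()]: error (default) or warn
#'   on surface/text mismatch.
#' @return An [annotated_document()].
#' @examples
#' doc <- parse_ann("abcdef", "T1\tdisease 2 5\tcde")
#' doc$spans
#' @export
parse_ann <- function(text, ann_lines, doc_id = "doc", strict = TRUE) {
  ann_lines <- ann_lines[nzchar(trimws(ann_lines))]
  keep <- grepl("^T", ann_lines)
  rows <- lapply(ann_lines[keep], function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_emrkg("malformed annotation line (expect 3 tab fields): %s", line)
    }
    mid <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(mid) != 3 || anyNA(suppressWarnings(as.integer(mid[2:3])))) {
      stop_emrkg("malformed annotation line (expect '<type> <start> <end>'): %s",
                 line)
    }
    data.frame(span_id = parts[1], entity_type = mid[1],
               start = as.integer(mid[2]), end = as.integer(mid[3]),
               surface = parts[3], stringsAsFactors = FALSE)
  })
  spans <- if (length(rows)) do.call(rbind, rows) else empty_spans()
  if (nrow(spans) && any(spans$end > nchar(text) | spans$start < 0)) {
    bad <- spans$span_id[spans$end > nchar(text) | spans$start < 0][1]
    stop_emrkg("span %s has offsets outside the text (length %d)",
               bad, nchar(text))
  }
  annotated_document(doc_id, text, spans, strict = strict)
}

#' Serialize a document's spans to BRAT entity lines
#'
#' Inverse of [parse_ann()]: emits one `T` line per span in span-id order.
#'
#' @param doc An [annotated_document()].
#' @return Character vector of annotation lines.
#' @export
write_ann <- function(doc) {
  stopifnot(inherits(doc, "annotated_document"))
  s <- doc$spans
  if (!nrow(s)) return(character())
  sprintf("%s\t%s %d %d\t%s", s$span_id, s$entity_type, s$start, s$end,
          s$surface)
}

#' Read / write a BRAT corpus directory
#'
#' A BRAT corpus is a directory of paired `<doc>.txt` / `<doc>.ann` files.
#' `write_brat()` writes one pair per document; `read_brat()` reads every
#' pair back (documents ordered by file name).
#'
#' @param docs List of [annotated_document()] objects.
#' @param dir Directory path (created if missing).
#' @param strict Passed to [parse_ann()].
#' @return `read_brat()` returns a list of documents; `write_brat()`
#'   returns `dir` invisibly.
#' @export
write_brat <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in docs) {
    writeLines(doc$text, file.path(dir, paste0(doc$doc_id, ".txt")),
               useBytes = FALSE)
    writeLines(write_ann(doc), file.path(dir, paste0(doc$doc_id, ".ann")))
  }
  invisible(dir)
}

#' @rdname write_brat
#' @export
read_brat <- function(dir, strict = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tf) {
    af <- sub("\\.txt$", ".ann", tf)
    if (!file.exists(af)) stop_emrkg("missing annotation file %s", af)
    text <- paste(readLines(tf, encoding = "UTF-8"), collapse = "\n")
    parse_ann(text, readLines(af, encoding = "UTF-8"),
              doc_id = sub("\\.txt$", "", basename(tf)), strict = strict)
  })
}

#' Tokenizers
#'
#' A tokenizer maps text to a data.frame of 0-based, end-exclusive token
#' offsets (columns `start`, `end`). `char_tokenizer()` emits one token per
#' character — the standard unit for Chinese sequence labeling and the
#' package default. `whitespace_tokenizer()` splits on runs of whitespace
#' (whitespace is not covered by any token).
#'
#' @param text Character scalar.
#' @return data.frame with integer columns `start`, `end`.
#' @export
char_tokenizer <- function(text) {
  n <- nchar(text)
  data.frame(start = seq_len(n) - 1L, end = seq_len(n))
}

#' @rdname char_tokenizer
#' @export
whitespace_tokenizer <- function(text) {
  if (!nzchar(text)) return(data.frame(start = integer(), end = integer()))
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Construct a tag sequence
#'
#' A tokenized sentence with aligned BIO labels and per-token character
#' offsets. Validates the length contract and (optionally) BIO validity:
#' an `I-x` label may only follow `B-x` or `I-x`.
#'
#' @param tokens Character vector of token strings.
#' @param labels Character vector of BIO tags (`"O"`, `"B-<type>"`,
#'   `"I-<type>"`), same length as `tokens`.
#' @param char_offsets Integer matrix with one `(start, end)` row per token
#'   (0-based, end-exclusive). Defaults to contiguous offsets from token
#'   lengths.
#' @param validate Check BIO validity (default `TRUE`).
#' @return Object of class `tag_sequence`.
#' @export
tag_sequence <- function(tokens, labels, char_offsets = NULL,
                         validate = TRUE) {
  stopifnot(length(tokens) == length(labels))
  if (is.null(char_offsets)) {
    ends <- cumsum(nchar(tokens))
    char_offsets <- cbind(start = c(0L, ends[-length(ends)]), end = ends)
    if (!length(tokens)) char_offsets <- cbind(start = integer(), end = integer())
  }
  char_offsets <- matrix(as.integer(char_offsets), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(char_offsets) == length(tokens))
  if (validate && length(labels)) {
    bad <- bio_violations(labels)
    if (length(bad)) {
      stop_emrkg("invalid BIO transition at position(s) %s: %s",
                 paste(bad, collapse = ", "),
                 paste(labels[bad], collapse = ", "))
    }
  }
  structure(list(tokens = tokens, labels = labels,
                 char_offsets = char_offsets),
            class = "tag_sequence")
}

# positions whose I- label does not continue a same-type entity
bio_violations <- function(labels) {
  prev <- c("O", labels[-length(labels)])
  is_i <- startsWith(labels, "I-")
  type <- sub("^[BI]-", "", labels)
  prev_type <- sub("^[BI]-", "", prev)
  which(is_i & !(prev != "O" & prev_type == type))
}

#' Validate a BIO label vector
#'
#' @param labels Character vector of BIO tags.
#' @return `TRUE` if every `I-x` continues a `B-x`/`I-x` run.
#' @export
is_bio_valid <- function(labels) length(bio_violations(labels)) == 0

#' @export
print.tag_sequence <- function(x, ...) {
  cat(sprintf("<tag_sequence: %d tokens, %d entity tokens>\n",
              length(x$tokens), sum(x$labels != "O")))
  invisible(x)
}

#' Convert entity spans to BIO tag sequences
#'
#' Tokenizes the document (default: per character), splits it into
#' sentences, and labels the first token overlapping each span `B-<type>`
#' and subsequent overlapping tokens `I-<type>`; all other tokens are
#' `"O"`. A span crossing a sentence boundary is an error naming the span.
#'
#' @param doc An [annotated_document()].
#' @param tokenizer Token-boundary function, see [char_tokenizer()].
#' @param sentence_split Regular expression of sentence terminators (the
#'   terminator stays with its sentence); `NULL` keeps the document as a
#'   single sequence. Default splits on the CJK full stop.
#' @return List of [tag_sequence()] objects with document-absolute
#'   character offsets.
#' @export
spans_to_bio <- function(doc, tokenizer = char_tokenizer,
                         sentence_split = "。") {
  stopifnot(inherits(doc, "annotated_document"))
  bounds <- sentence_bounds(doc$text, sentence_split)
  spans <- doc$spans
  lapply(seq_len(nrow(bounds)), function(si) {
    s0 <- bounds$start[si]; e0 <- bounds$end[si]
    toks <- tokenizer(substr0(doc$text, s0, e0))
    toks$start <- toks$start + s0
    toks$end <- toks$end + s0
    labels <- rep("O", nrow(toks))
    in_sent <- spans$start < e0 & spans$end > s0
    cross <- in_sent & (spans$start < s0 | spans$end > e0)
    if (any(cross)) {
      stop_emrkg("span(s) %s cross a sentence boundary in %s",
                 paste(spans$span_id[cross], collapse = ", "), doc$doc_id)
    }
    for (k in which(in_sent)) {
      hit <- which(toks$start < spans$end[k] & toks$end > spans$start[k])
      if (!length(hit)) next
      labels[hit[1]] <- paste0("B-", spans$entity_type[k])
      if (length(hit) > 1) {
        labels[hit[-1]] <- paste0("I-", spans$entity_type[k])
      }
    }
    tag_sequence(vapply(seq_len(nrow(toks)),
                        function(i) substr0(doc$text, toks$start[i], toks$end[i]),
                        character(1)),
                 labels, cbind(toks$start, toks$end))
  })
}

sentence_bounds <- function(text, sentence_split) {
  n <- nchar(text)
  if (is.null(sentence_split) || !n) {
    return(data.frame(start = 0L, end = n))
  }
  cs <- chars(text)
  ends <- which(grepl(sentence_split, cs))
  if (!length(ends) || ends[length(ends)] != n) ends <- c(ends, n)
  starts <- c(0L, ends[-length(ends)])
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Recover entity spans from a BIO tag sequence
#'
#' Inverse of [spans_to_bio()] for contiguous tokenizations: each maximal
#' `B-x (I-x)*` run becomes a span covering the run's character range, with
#' surface equal to the concatenated token strings. With per-character
#' tokenization, `bio_to_spans(spans_to_bio(doc))` reproduces `doc$spans`.
#'
#' @param seq A [tag_sequence()].
#' @param strict If `TRUE` (default) an invalid BIO transition is an error
#'   with its position; if `FALSE`, a dangling `I-x` starts a new span
#'   (conventional repair).
#' @param id_offset Spans are numbered `T<id_offset+1>`, ... .
#' @return data.frame of spans (`span_id`, `entity_type`, `start`, `end`,
#'   `surface`).
#' @export
bio_to_spans <- function(seq, strict = TRUE, id_offset = 0L) {
  stopifnot(inherits(seq, "tag_sequence"))
  labels <- seq$labels
  if (strict && length(labels)) {
    bad <- bio_violations(labels)
    if (length(bad)) {
      stop_emrkg("invalid BIO transition at position %d (%s)", bad[1],
                 labels[bad[1]])
    }
  }
  out <- empty_spans()
  run_start <- NA_integer_
  run_type <- NA_character_
  flush <- function(i_end) {
    if (is.na(run_start)) return()
    idx <- run_start:i_end
    out[nrow(out) + 1L, ] <<- list(
      sprintf("T%d", id_offset + nrow(out) + 1L), run_type,
      seq$char_offsets[run_start, "start"], seq$char_offsets[i_end, "end"],
      paste(seq$tokens[idx], collapse = ""))
  }
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") {
      flush(i - 1L); run_start <- NA_integer_
    } else {
      type <- sub("^[BI]-", "", lab)
      if (startsWith(lab, "B-") || is.na(run_start) || type != run_type) {
        flush(i - 1L)
        run_start <- i; run_type <- type
      }
    }
  }
  flush(length(labels))
  out
}

#' Read / write a BIO corpus (CoNLL-style TSV)
#'
#' One `token<TAB>label` line per token, a blank line between sequences.
#' Character offsets are not stored in the format; on reading they are
#' reconstructed from cumulative token lengths within each sequence.
#'
#' @param seqs List of [tag_sequence()] objects.
#' @param path File path.
#' @return `read_bio()` returns a list of tag sequences; `write_bio()`
#'   returns `path` invisibly.
#' @export
write_bio <- function(seqs, path) {
  blocks <- vapply(seqs, function(s) {
    paste(sprintf("%s\t%s", s$tokens, s$labels), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_bio
#' @export
read_bio <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  breaks <- c(0L, which(!nzchar(lines)), length(lines) + 1L)
  seqs <- list()
  for (b in seq_len(length(breaks) - 1L)) {
    block <- lines[seq(breaks[b] + 1L, breaks[b + 1L] - 1L)]
    block <- block[nzchar(block)]
    if (!length(block)) next
    parts <- strsplit(block, "\t", fixed = TRUE)
    seqs[[length(seqs) + 1L]] <- tag_sequence(
      vapply(parts, `[`, character(1), 1),
      vapply(parts, `[`, character(1), 2))
  }
  seqs
}

#' Split a corpus into train / validation / test partitions
#'
#' Document-level random split. Partition sizes are `floor(n * ratio)` with
#' the remainder allocated by largest fractional part (ties toward earlier
#' partitions), so a 10-document corpus at ratios `c(.8, .1, .1)` yields
#' sizes 8/1/1. The split is deterministic given `seed` and leaves the
#' global RNG state untouched.
#'
#' @param docs List (any element type).
#' @param ratios Numeric vector summing to 1.
#' @param seed Integer seed.
#' @return Named list of disjoint lists `train`, `dev`, `test` (or
#'   `part1..k` if `ratios` has length other than 3) whose union is `docs`.
#' @export
split_dataset <- function(docs, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(is.numeric(ratios), all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-8) stop_emrkg("ratios must sum to 1")
  n <- length(docs)
  if (n < sum(ratios > 0)) {
    stop_emrkg("fewer documents (%d) than nonzero partitions (%d)",
               n, sum(ratios > 0))
  }
  sizes <- floor(n * ratios)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * ratios - sizes
    ord <- order(-frac, seq_along(ratios))
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  perm <- withr::with_seed(seed, sample.int(n))
  cuts <- cumsum(sizes)
  starts <- c(0L, cuts[-length(cuts)])
  parts <- lapply(seq_along(sizes), function(i) {
    if (sizes[i] == 0) list() else docs[perm[(starts[i] + 1L):cuts[i]]]
  })
  names(parts) <- if (length(sizes) == 3) c("train", "dev", "test") else
    paste0("part", seq_along(sizes))
  parts
}
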