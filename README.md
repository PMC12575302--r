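# emrkg

Clinical notes hold most of what is known about a patient, but they hold
it as free text. `emrkg` is an R toolkit for turning annotated electronic
medical records (EMRs) — for instance liver-cancer admission notes,
surgical records and discharge summaries — into a schema-validated
medical knowledge graph (KG), and for measuring how much the result can
be trusted. It is written for clinical-NLP practitioners and informatics
researchers who need the whole chain — corpus handling, entity
recognition, terminology normalization, graph assembly, quality audit —
reproducible on a single CPU without private data or external services.

## What is inside

* **Corpus I/O** — BRAT standoff annotations (`.txt`/`.ann` pairs,
  0-based end-exclusive character offsets) parsed and validated against
  the text; conversion between entity spans and BIO tag sequences;
  CoNLL-style TSV; seeded document-level train/dev/test splits.
* **DERM augmentation** — dynamic entity replacement and masking: per
  training sequence a random number RN selects a branch — RN < 0.3
  replaces every entity mention with a same-type dictionary term,
  0.3 ≤ RN < 0.6 masks entity tokens, RN ≥ 0.6 keeps the sequence.
* **Sequence labeler** — a toy-scale transformer encoder
  (`E_input = E_t + E_p + E_s`, scaled dot-product attention
  `softmax(QKᵀ/√d_k)V`, multi-head concat + projection) feeding a
  BiLSTM (`h_i = [h→_i; h←_i] ∈ R^{2h}`, emissions `S_i = W h_i + b`)
  and a linear-chain CRF:

      Score(X, y) = Σᵢ S[i, yᵢ] + Σᵢ T[yᵢ, yᵢ₊₁]
      p(y|X) = exp Score(X, y) / Σ_y′ exp Score(X, y′)
      y* = argmax_y Score(X, y)

  with a log-space forward algorithm, BIO-constrained exact Viterbi
  decoding, and full handwritten backpropagation (verified against
  finite differences in the tests).
* **Evaluation** — exact-match entity P/R/F1 (`F1 = 2PR/(P+R)`), micro
  and per-type.
* **Knowledge fusion** — character n-gram TF-IDF
  (`TF(t,d) = f_{t,d}/f_d`, `IDF(t) = log(N/|{d : t∈d}|)`) with cosine
  matching against reference terminologies and three decision tiers:
  similarity > 0.75 maps automatically, 0.6–0.75 (inclusive) queues for
  human review, < 0.6 is rejected.
* **KG builder** — 11 entity types and an 18-relation schema (shipped as
  editable config), patient-centric triple assembly with validation and
  deduplication, bulk-import CSV and Cypher export with exact
  round-trips, multi-hop retrieval such as
  patient → `rels_disease` → disease → `accompany_with` → complication.
* **Quality audit** — stratified triple sampling and triple accuracy
  `TAcc = x / n_eff` with `n_eff = sampled − insufficient-context`.
* **Synthetic-EMR generator** — seeded dictionaries, annotated corpora
  with exact gold spans, variant query/canonical pairs, and labeled QA
  samples, so the pipeline is fully testable without clinical data.

## Worked example

```r
library(emrkg)

# a synthetic annotated corpus with exact gold spans
cfg   <- generator_config(n_docs = 400, mentions_per_doc = 2, seed = 1)
dicts <- generate_dictionaries(cfg)
docs  <- generate_corpus(cfg, dicts)
parts <- split_dataset(docs, c(0.8, 0.1, 0.1), seed = 1)
seqs  <- function(d) unlist(lapply(d, spans_to_bio), recursive = FALSE)

# train the DERM-augmented transformer + BiLSTM-CRF stack from scratch
model <- fit_labeler(seqs(parts$train), encoder = "transformer",
                     epochs = 4, seed = 42,
                     derm = derm_config(dicts, seed = 42))
round(evaluate_labeler(model, seqs(parts$test))$metrics, 2)
#> precision    recall        f1
#>       100       100       100

# normalize a clipped disease variant against the reference terminology
ref <- fit_tfidf(dicts$disease)
map_entity(substr(dicts$disease[3], 1, nchar(dicts$disease[3]) - 1), ref)
#>            query       best_match similarity tier
#> 1 丢丢中丒丬上丏 丢丢中丒丬上丏丧  0.9340834 auto

# assemble the patient-centric knowledge graph
store <- assemble_kg(parts$test, proxy = FALSE)
store
#> <triple_store: 118 entities (5 types), 80 triples (4 relations)>
```

The held-out F1 of 100 % reflects the generator's deliberately strong
lexical cues (each entity type has its own character block): it shows
the optimization and decoding are correct, not that real clinical
corpora are this easy. The fusion call maps a truncated term back to its
canonical dictionary entry with cosine similarity 0.93, above the 0.75
automatic-mapping threshold.

A triple-accuracy audit from per-stratum counts:

```r
counts <- data.frame(
  stratum = c("has_symptom", "accompany_with", "recommand_drug",
              "recommand_eat", "rels_diseases"),
  sampled = c(160L, 110L, 90L, 80L, 60L),
  ic      = c(2L, 3L, 2L, 2L, 1L),
  correct = c(149L, 100L, 82L, 72L, 55L))
triple_accuracy(qa_sample_from_counts(counts))[, c("stratum", "n_eff",
                                                   "accuracy_pct")]
#>          stratum n_eff accuracy_pct
#> 1    has_symptom   158        94.30
#> 2 accompany_with   107        93.46
#> 3 recommand_drug    88        93.18
#> 4  recommand_eat    78        92.31
#> 5  rels_diseases    59        93.22
#> 6        Overall   490        93.47
```

`accuracy_pct` is `100 * correct / n_eff` rounded half-up to two
decimals; insufficient-context triples are excluded from the ratio and
reported separately.

A command-line interface (`exec/emrkg`) wraps the same functions:
`simulate`, `convert`, `split`, `augment`, `fuse`, `build-kg`, `query`
and `qa-score` subcommands.

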