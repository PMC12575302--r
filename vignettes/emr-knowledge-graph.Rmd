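---
title: "Building clinical knowledge graphs from annotated EMRs with emrkg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building clinical knowledge graphs from annotated EMRs with emrkg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emrkg` implements a complete desk-scale pipeline for turning annotated
clinical notes — for example, liver-cancer electronic medical records
(EMRs) annotated with diseases, symptoms, operations and treatments —
into a schema-validated medical knowledge graph (KG), together with the
quality instruments needed to trust the result. This vignette explains
the models and procedures, the parameters that matter, and the design
choices made where the design was genuinely open.

```{r setup}
library(emrkg)
```

## The pipeline at a glance

1. **Corpus I/O** — BRAT standoff annotations (paired `.txt`/`.ann`
   files with 0-based, end-exclusive character offsets) are parsed,
   validated against the text, converted to BIO tag sequences, and split
   into train/dev/test partitions at the document level.
2. **DERM augmentation** — a stochastic training-set transform that
   replaces or masks entity mentions to combat data scarcity.
3. **Sequence labeling** — a toy-scale transformer encoder feeding a
   BiLSTM emission layer and a linear-chain CRF with exact Viterbi
   decoding.
4. **Knowledge fusion** — TF-IDF cosine matching of variant entity
   surface forms against reference terminologies, with a three-tier
   auto / review / reject decision.
5. **KG assembly** — patient-centric triples validated against an
   11-type, 18-relation schema; bulk-import CSV and Cypher export;
   multi-hop retrieval.
6. **Quality audit** — stratified triple sampling and triple accuracy
   with insufficient-context exclusion.

A seeded synthetic-EMR generator stands in for private clinical data, so
every stage is exercised end to end by reproducible tests.

## Sequence labeling model

### Emissions

Token sequences are embedded as the elementwise sum of token, position
and segment vectors and passed through a stack of self-attention encoder
blocks (`encode()`): scaled dot-product attention
`softmax(QK'/sqrt(d_k))V`, multiple heads concatenated and projected.
Each block additionally carries a residual connection, layer
normalization, and a position-wise feed-forward sublayer. The bare
attention equations alone do not train stably from scratch, so these
standard completions are included; we use the pre-norm arrangement
(normalization before each sublayer) because it optimizes reliably
without a warmup schedule at small scale. The default scale is
deliberately tiny — `d_model = 16`, 2 layers, 2 heads — because the
package trains from scratch on a desktop CPU; production systems would
substitute a large pretrained encoder behind the same
"tokens in, context vectors out" contract, which is also satisfied by
the plain lookup embedder (`init_lookup_encoder()`) used in fast tests.

A bidirectional LSTM (`bilstm_hidden()`) then produces, at each
position, the concatenation `h_i` of a forward and a backward hidden
state (width `2h`, default `h = 16`), and an affine map gives one
emission score per label: `S_i = W h_i + b`.

### The CRF layer

Instead of classifying tokens independently, the conditional random
field scores whole label sequences:

$$\mathrm{Score}(X, y) = \sum_{i=1}^{n} S_{i,y_i} +
  \sum_{i=1}^{n-1} T_{y_i, y_{i+1}},$$

with `T` a learned label-transition matrix, and normalizes over all
sequences, `p(y|X) = exp(Score) / \sum_{y'} exp(Score')`. The partition
sum is computed by the forward algorithm in log space with log-sum-exp
stabilization (the probability-space recursion overflows for all but the
shortest sequences). Decoding is exact Viterbi; ties break toward the
lowest label index so decoding is reproducible. BIO transition
constraints (`I-x` only after `B-x`/`I-x`) are enforced by additive
`-Inf` masking and are on by default, so decoded label sequences are
always well-formed; optional start/stop boundary scores are learned
during training but excluded from the two-term score definition above,
entering as separate additive arguments so the enumeration oracle and
the forward algorithm share one convention. The special `[CLS]`/`[SEP]`
positions carry no labels and are excluded from the emissions and loss.

Training minimizes the mean negative log-likelihood by mini-batch Adam
(defaults: 6 epochs, learning rate 0.01, batch 8, global-norm clip 5 —
package defaults, not tuned to any reference run), with handwritten
reverse-mode gradients through the CRF (forward–backward expected
counts), both LSTM directions, the attention stack and the embedding
tables. The gradients are verified against central finite differences in
the test suite.

### Tokenization

The default unit is the character, the standard choice for Chinese
clinical text; subword (BPE-style) vocabularies are supported through
the pluggable tokenizer and vocabulary since nothing downstream assumes
single-character tokens. We default to characters because
whole-word-style Chinese encoders conventionally consume characters and
because character tokens make the span/label alignment exact.

## DERM augmentation

For every training sequence a random number RN in (0,1) picks one of
three branches: **replace** (RN < 0.3) swaps each entity mention's
surface for a uniformly drawn same-type dictionary term (excluding the
original when alternatives exist, to avoid no-op replacements), with
labels re-aligned to the new length; **mask** (0.3 ≤ RN < 0.6) replaces
each entity token with `[MASK]`, one mask per token so labels are
untouched; **keep** (RN ≥ 0.6) leaves the sequence alone. Non-entity
tokens are never modified.

Two points were genuinely open and are resolved as follows. The
per-sequence RN governs all mentions in the sequence uniformly (a
per-mention mode exists behind `per_mention = TRUE`), since the
procedure is described per sequence. And augmentation is re-sampled
every epoch by default (`derm_mode = "epoch"`) — "during training"
suggests a dynamic transform, and re-sampling exposes the model to more
entity variety; a single up-front pass is available as `"once"`. The
injectable `rng_value` argument exists purely so each branch is
unit-testable deterministically.

## Knowledge fusion

Different clinicians record the same entity differently (e.g.
原发性肝细胞癌 vs 原发性肝癌), so recognized entities are normalized
against reference terminologies. Each canonical reference term is
treated as one document; features are character n-grams (default sizes
1–2, chosen because shared-substring structure is exactly what
distinguishes variant clinical terms; the featurization unit is
configurable). Weights follow the literal formulas: TF is the feature
count divided by the term's total feature count (so TF within a term
sums to 1) and IDF is the unsmoothed natural log of the term count over
the document frequency — an add-one smoothing flag exists for degenerate
corpora. Queries are vectorized with the reference-fitted IDF, the
standard practice when the query side has no corpus of its own.

A query maps to the reference term with the highest cosine similarity
(ties to the lexicographically smallest term). The decision tiers follow
the printed boundary semantics exactly: strictly above 0.75 maps
automatically, `[0.6, 0.75]` inclusive goes to a human review queue
(never auto-merged), below 0.6 is rejected as a different entity.
Disease and symptom entities route to the website-style reference
corpus, treatment and operation entities to the terminology standard;
unrouted types pass through verbatim.

## KG schema and assembly

The conceptual layer registers 11 entity types (patient, examination,
symptom, disease, past history, operation recording, treatment options,
physical examination, food, drug, department) and 18 relations. The
relation inventory ships in `inst/extdata/kg_relations.tsv` with
domain/range pairs; these pairs are not fully documented anywhere
authoritative, so they are inferred — the seven `rels_*` patient-record
relations are registered patient→category, the website relations
(`has_symptom`, `recommand_drug`, `accompany_with`, food relations,
`need_check`) disease→X, and `belongs_to` carries wildcard endpoints
because it serves both department membership and hub edges — and live in
a config file precisely so corrections need no code change. Both
`rels_disease` and `rels_diseases` are registered verbatim as distinct
relations, as inventoried upstream.

Assembly is patient-centric: each document contributes a patient node
linked to its (canonicalized) entity mentions. By default a per-patient
category hub node sits between the patient and its specific entities
(`patient -rels_disease-> hub -belongs_to-> disease`), mirroring how
per-patient subgraphs are usually visualized; `proxy = FALSE` links
directly, which is the convenient mode for path queries like
patient → `rels_disease` → disease → `accompany_with` → complication.
Duplicate triples collapse (assembly is idempotent), schema-invalid
triples are dropped and reported, and referential integrity (no dangling
endpoints) holds by construction. Export targets the bulk-import CSV
header convention (`id:ID`, `type:LABEL`, `:START_ID`, `:TYPE`,
`:END_ID`) and a Cypher `MERGE` script; both round-trip exactly, so no
database server is needed anywhere in the pipeline.

## Quality audit

Graph quality is quantified by triple accuracy over a stratified random
sample: per relation stratum, `n_eff = sampled − IC` counts the
evaluable triples after excluding insufficient-context items, and
`TAcc = x / n_eff` with `x` the triples judged correct. The overall row
pools counts across strata (a pooled ratio, not a mean of stratum
accuracies), and the IC proportion is reported separately as a
documentation-completeness indicator. Reported percentages round half-up
to two decimals, matching how such audit tables are printed; full
precision is retained internally. Stratum sizes are free configuration
(the shipped default audits 500 triples across the five major
relations: 160/110/90/80/60) since no principled allocation is
documented. The package never auto-labels correctness: labels come from
annotators, or from the synthetic generator when testing the arithmetic.

```{r}
counts <- data.frame(
  stratum = c("has_symptom", "accompany_with", "recommand_drug",
              "recommand_eat", "rels_diseases"),
  sampled = c(160L, 110L, 90L, 80L, 60L),
  ic      = c(2L, 3L, 2L, 2L, 1L),
  correct = c(149L, 100L, 82L, 72L, 55L))
triple_accuracy(qa_sample_from_counts(counts))[, c("stratum", "sampled",
                                                   "ic", "n_eff",
                                                   "accuracy_pct")]
```

## The synthetic-EMR generator

Real clinical corpora are private, so all tests run on generated data
with exact gold structure. Each entity type draws terms (2–10
characters) from its own disjoint 64-character CJK block; carrier text
comes from a separate filler block. Documents embed a configured number
of dictionary mentions (default 3) with types drawn from a uniform
multinomial, and gold spans are recorded during construction, so every
downstream statistic can be audited against generator bookkeeping.
Variant pairs for fusion testing apply one logged surface edit per term;
the default rule mix (identity 0.1, drop-last 0.3, append 0.3,
substitute-last 0.3, applied to terms of length ≥ 4) models light
terminal affix variation, the dominant mode of clinical term variants.
QA label simulation defaults to 93.5 % accuracy and a 2 % IC rate, the
regime a well-built graph audit reports.

What the generator deliberately does **not** model: linguistic realism
of the carrier text, EMR section structure, nested or discontinuous
entities, ambiguous mentions shared across types, and annotation noise.
The per-type disjoint alphabets make entity types lexically separable —
a strong cue. Consequently, passing recovery tests demonstrates that the
optimization, decoding and bookkeeping are correct, not that the model
would reach comparable scores on real clinical text, where reported
scores depend on large pretrained encoders and private data.

## Numerical choices and problem sizes

* Partition and marginals in log space; `-Inf` masks for forbidden
  transitions; Viterbi ties to the lowest label index.
* Zero-denominator conventions: precision/recall/F1 return 0 with a
  warning; cosine similarity of a zero vector is 0; a stratum with
  `n_eff = 0` reports `NA` accuracy.
* Overlapping annotation spans are rejected by default (the schema has
  no nested-entity semantics); a keep-longest repair mode exists.
* Dataset splits allocate `floor(n * ratio)` per partition and assign
  the remainder by largest fractional part, so a 10-document corpus at
  0.8/0.1/0.1 splits 8/1/1.
* The test suite's end-to-end recovery experiment uses 2,000 generated
  documents (8:1:1 split, ~20-character sequences, 2 mentions each) and
  5 training epochs — sizes chosen so the full stack trains from scratch
  in about a minute per fit on one CPU while leaving no doubt about
  convergence; the CRF is verified against exhaustive enumeration on
  1,000 random small instances.

## Limitations

The encoder is a toy: no pretraining, whole-word masking, or subword
vocabulary learning is included, and published large-model scores are
out of reach (and out of scope) at this scale. Fusion is lexical;
semantically equivalent terms sharing no characters will not map (an
embedding-based linker would be the natural upgrade). De-identification
is rule-based replacement only and makes no guarantees about free-text
identifiers beyond the configured patterns. Relation domain/range pairs
are inferred, not authoritative — they are config, not code, for exactly
that reason.
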