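---
title: "Event trigger recognition with per-type CRFs: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event trigger recognition with per-type CRFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trigtag)
```

## Scope and assumptions

trigtag recognizes event triggers — the textual predicates of biomolecular
events — in text that has already been pre-processed by an external NLP
stage. The package consumes that stage's output (tokens with character
offsets, lemmas, POS tags, BIO chunk tags, dependency heads and labels, in
a 9-column token table) and never re-implements it. Likewise, concept
mentions (proteins and other entities that events attach to) are inputs:
they are loaded from A1 standoff files or matched from user dictionaries,
not predicted by machine learning here.

Two assumptions follow. First, tokenization fixes the granularity of every
downstream decision: triggers are token-aligned spans, and gold spans that
cross token boundaries are treated as data errors. Second, the dependency
parse is taken at face value; its edges are stored as an undirected labeled
graph for path queries, while the head→dependent direction is retained as
edge metadata because the modifier and in/out-dependency features need it.

## The sequence model

Each event type gets its own linear-chain CRF over BIO labels
(`B`/`I`/`O`). For observations $x$ (per-token feature strings) and labels
$y$,

$$p(y \mid x, \lambda) = \frac{1}{Z(x)} \exp \sum_j \lambda_j F_j(y, x),$$

with $F_j$ summing state and transition feature functions along the chain.
Weights are estimated by maximizing the L2-penalized conditional
log-likelihood; decoding is exact Viterbi.

Training one model per type has two consequences this package leans on:
a token can be a trigger of several event types at once (each model
contributes its own span to the sentence's annotation tree), and each
model's feature set can be tuned to its type's linguistic profile.

**Higher orders.** A model of order $o > 1$ conditions each label on the
$o-1$ previous labels. Rather than a native higher-order engine, the chain
is reduced to a first-order equivalent over composite labels
(`raise_order()`: position $t$ carries the concatenation of the previous
$\min(o-1, t-1)$ labels and its own). A static transition mask admits only
composites whose prefix equals the predecessor's suffix and whose length
grows by one until it reaches $o$; a start mask admits only
single-component labels at the first position. The reduction is
behavior-equivalent for training and decoding, which the test suite checks
by exhaustive enumeration of all mask-legal label sequences on short
sentences.

**Numerical choices.** The Gaussian prior has variance 1.0 (exposed as a
`crf_train()` argument); L-BFGS runs at most 200 iterations with a relative
objective tolerance of $10^{-5}$; weights start at zero. Training is
deterministic given the data ordering, so fitted weights are
bit-reproducible. Viterbi ties break toward the lowest label index, and
shortest-path ties (below) break lexicographically, so extracted features
and decoded spans never depend on hash or iteration order. A predicted `I`
directly after `O` opens a new span at decoding time (the encoder never
produces that pattern, the decoder tolerates it). Overlapping same-type
gold spans are resolved to the longest span before encoding. A training set
with zero positive spans trains (all-`O` behavior) but logs a
degenerate-model warning.

## The feature catalogue

All features are categorical `KEY=value` strings; every numeric quantity
(counts, lengths, hop distances) is emitted as such a string, consistent
with a discrete-feature CRF. The families, each independently switchable in
a `trig_config`:

* **token** — text, lemma, POS, BIO chunk tag.
* **orthographic** — capitalization classes (`InitUpp`, `AllUpp`,
  `MixCase`, `AllLow`), counts of uppercase characters and digits, token
  length, symbol-occurrence tags.
* **morphological** — prefixes and suffixes of lengths 2–4 (the cited
  recognizer heritage fixes this range; only tokens at least as long emit
  an affix), character n-grams at the configured sizes, and the word shape
  (uppercase→`A`, lowercase→`a`, digit→`1`, other→`#`; `Abc:1234` →
  `Aaa#1111`).
* **sentence length** — one of seven bins: fewer than 15 tokens, then
  5-token bins up to 40, then 40 or more. Bins are lower-inclusive /
  upper-exclusive (a 15-token sentence falls in `[15,20)`); the prose
  description of such bins is ambiguous at the boundary, and a fixed
  convention matters more than which one.
* **concepts** — per-token concept-type tags; per-sentence broadcast of
  concept names (spaces replaced by `_`), concept head tokens, and
  per-type mention counts. The concept "head" is the first token of the
  mention (matching the worked example, `CONCEPT_PROTEIN_HEAD=interferon`);
  linguistic head finding is out of scope.
* **dictionary** — `Trigger=<type>` on tokens covered by a dictionary
  match.
* **modifier** — lemmas of verbs the token is subject/object of, nouns it
  modifies, and its own modifiers, read off the directed edge metadata and
  POS prefixes.
* **dependency edges** — for each edge at a token, the label plus the
  opposite endpoint's lemma, POS and chunk, split into input dependencies
  (the token is the dependent) and output dependencies (the token is the
  head). This orientation is a single calibrated switch: it is the
  assignment under which the worked example reproduces its documented
  `IN_DEP_*`/`OUT_DEP_*` values.
* **shortest path** — for each token, the minimum-hop undirected path to
  the closest concept token (ties: smallest target token index), within the
  configured hop limit (default 3): edge-label path, edge type (first label
  + hop count), vertex path over the configured vertex information (lemma
  by default; token/POS/chunk as alternatives), edge and vertex n-grams,
  and the hop distance itself (`SPDistance`). Path n-grams are emitted only
  for paths with at least two edges — a one-edge path's n-grams would
  duplicate the path features verbatim. Token-pair paths other than
  token↔closest-concept are not emitted; in/out edge features already
  cover the 1-hop relations.

**Context modes** (one active per model): `none`; local windows (copying
token/lemma/POS/chunk of neighbors at offsets −3…+1); conjunctions
(joined lemma or POS values over the windows {−3,−1}, {−2,−1}, {−1,0},
{−1,1}, {0,1}, e.g. `interferon@-1_&_factor@1`); dependency windows
(lemma/POS/chunk of all tokens within ≤3 graph hops).

**Union-then-filter.** When several models annotate one corpus, features
are extracted once under the union of their configurations and filtered
per model. Every parameter that optimization can vary is encoded in the
feature key (`CHARNG3=`, `SP_VERTEX_NG2_LEMMA=`, `DW1_POS=`), so filtering
is a pure string operation plus a per-token hop-limit check; context is
applied per model after filtering, since context modes do not union. The
central correctness property — filtering a union extraction is identical
to direct extraction — is tested over randomized corpora.

## The greedy optimizer

Per event type, over a document-level random train/development split
(default ratio 0.75; document-level so sentences of one abstract never
straddle the split):

1. a forward pass over the feature families in catalogue order (token,
   orthographic, morphological, sentence length, concepts, dictionary,
   modifier, dependency edges, shortest path) — a family stays active only
   if it strictly improves dev micro-F1 (ties reject: prefer the simpler
   model);
2. context-mode selection (the pre-optimization default is `none`);
3. n-gram-size selection for each retained n-gram-bearing family
   (default sizes {2,3});
4. hop-limit selection for each retained hop-bearing family (default 3);
5. vertex-information selection for path features (default lemma).

Every trial trains one model per candidate order and keeps the best
(F1 ties toward the lowest order). Families rejected in step 1 are skipped
in steps 3–5. There is no backtracking: earlier decisions are never
revisited. The order stored in the final configuration is the best order
of the last accepted trial; the final model is then retrained on the full
data set with that configuration. The audit log records every trial
(type, step, candidate, per-order F1, accepted), and the accepted-trial F1
sequence is non-decreasing by construction — the suite asserts this on
the log rather than trusting it.

## Dictionary matching and post-processing

Dictionary matching is case-insensitive exact matching of whole names,
aligned to token boundaries on both ends (so "press" never fires inside
"expression"); within one dictionary, matches nested in a longer match are
dropped, while different dictionaries report independently. Two rule
filters run after prediction: spans whose text contains an odd number of
round, square or curly brackets are removed (parity is evaluated per
bracket family — stricter than pooled counting, and a dangling bracket of
any family already indicates a span error), and all triggers in sentences
without any concept annotation are removed (an event needs an entity).
Both filters only ever remove annotations and are idempotent.

## Evaluation

Only exact span matching is scored: a prediction is correct iff a gold
span of the same type has identical start and end offsets (the vast
majority of triggers are single tokens, so approximate matching buys
little and blurs error analysis). TP/FP/FN counts are pooled before
computing precision, recall and F1 (micro-averaging), empty denominators
yield 0, and scores are reported on a 0–100 scale. Grouping presets pool
the five simple event types, binding, and the regulation family.

## The synthetic corpus generator

`generate_corpus()` emulates, at toy scale, exactly the structure the
recognizer exploits: per-type trigger lexicons whose words are gold
triggers in trigger-context templates; the same words as distractors in
noise contexts (`noise_rate`, default 0.2, the fraction of lexicon
emissions that are non-triggers); annotated protein mentions in every
trigger-bearing sentence; function-word filler; random projective
dependency trees labeled from a small GDep-like set ({SUB, OBJ, NMOD,
PMOD, VMOD}); and trigger-free sentences (`plain_rate` 0.2). Defaults —
20 documents of 8 sentences, two event types, noise 0.2 — are the study
conditions of the package's recovery experiments; the acceptance study
uses 40 × 8 = 320 sentences. Generation is byte-identical under a fixed
seed.

What the generator does **not** emulate: real biomedical lexical
diversity, ambiguous multi-type trigger words, long-range syntax, nested
or multi-token triggers, and realistic class imbalance. Green recovery
tests therefore certify the machinery (feature extraction, training,
decoding, optimization, evaluation), not corpus-scale accuracy; benchmark
figures require the externally distributed shared-task corpus via
`benchmark_bionlp()`.

## Conventions and degenerate inputs

Character offsets are 0-based and end-exclusive (standoff convention);
token indices are 0-based. A1 trigger writers allocate ids continuing
after the highest existing annotation id. Dictionary TSV files separate
names within the second field by `|`. The annotation tree keeps partially
overlapping spans as siblings flagged ambiguous rather than resolving
them. Disconnected token pairs yield an explicit no-path result (`NULL`),
not an error; a token inside a concept has a 0-hop closest-concept path
(hence `SPDistance=0` and no path features). Single-token sentences,
edge-free graphs, empty annotation streams and empty dictionaries are all
exercised in the tests.

## Worked-example calibration

The bundled example sentence freezes one tokenization and parse of
*"Down-regulation of interferon regulatory factor 4 gene expression in
leukemic cells."* (14 tokens; the hyphen is its own token with lemma "−"
and POS `HYPH`). Its documented feature values — the in/out dependencies
of "regulation", its 1-hop neighborhood {of, −, in}, and the 3-hop path
regulation–of–expression–4 — pin down only part of the parse; the
remaining edges were chosen once, frozen, and are relied on by nothing
but connectivity. Tests assert only the calibrated fragments.

## Problem sizes

The default test run trains CRFs on corpora of 100–300 short sentences,
enumerates label sequences exhaustively on sentences of up to 6 tokens
(4 for order 2), checks path queries against BFS on graphs of up to 12
vertices, and runs the optimizer over reduced spaces of 3–4 families and
1–2 orders — sizes at which every oracle stays exhaustive and the whole
suite completes in well under a minute of CPU.

## Known limitations

* Event arguments (the participants attached to a trigger) are out of
  scope; so is any A2 output.
* Semi-supervised training is not implemented.
* The higher-order reduction is prediction-equivalent to a native
  higher-order engine but not a byte-level reimplementation of one; orders
  beyond 3 multiply the composite alphabet and are impractical here.
* Dictionary matching is exact; no fuzzy or approximate matching.
* Whether a trigger word is "the closest" concept's predicate is decided
  purely by graph distance; semantic role information is not consulted.
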