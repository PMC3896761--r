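# trigtag

Biomedical event extraction starts with finding the **event triggers**: the
words or phrases that signal a molecular event and serve as its predicate —
"expression" for a `Gene_expression` event, "Down-regulation" for a
`Negative_regulation` event. trigtag recognizes such triggers in pre-parsed
scientific text. It is aimed at text-mining practitioners who already run an
NLP pre-processing stage (sentence splitting, tokenization, lemmatization,
POS tagging, chunking, dependency parsing) and need typed, character-offset
trigger annotations in BioNLP standoff form as input to event extraction.

Because the same word can trigger different event types in different
contexts (and a single token can trigger two events at once), trigtag trains
**one model per event type** and lets a greedy search tailor each model's
feature set and hyper-parameters to that type.

## The model

Each per-type model is a linear-chain conditional random field over
BIO-encoded token sequences. With an observation sequence *x* (the per-token
feature strings) and a label sequence *y*:

```
p(y | x, λ) = 1/Z(x) · exp Σⱼ λⱼ Fⱼ(y, x),   Fⱼ(y,x) = Σᵢ fⱼ(yᵢ₋₁, yᵢ, x, i)
```

where each *fⱼ* is a state or transition feature function, the weights λⱼ are
fit by L2-penalized maximum conditional likelihood (L-BFGS), and decoding is
exact Viterbi. Model order *o* > 1 (each label conditioning on the *o* − 1
previous labels) is realized by reducing the chain to a first-order
equivalent over composite labels, with a transition mask enforcing
composite consistency.

The feature catalogue covers token text/lemma/POS/chunk, orthographic and
morphological form (affixes, char n-grams, word shapes), sentence length,
concept annotations (tags, names, heads, counts), dictionary hits, and
dependency-parse features: modifier roles, in/out edges, and shortest paths
from each token to the closest concept mention (edge paths, vertex paths,
path n-grams, hop distances). Local context is modeled by feature windows,
conjunctions, or dependency-graph windows.

The greedy optimizer searches, per event type: the feature families (forward
pass, kept only on strict dev-F1 improvement), the context mode, n-gram
sizes, dependency-hop limits, vertex information, and the CRF order —
evaluated with exact-match micro-averaged F1 on a held-out document split.

## Worked example

The package bundles a fully parsed example sentence — *"Down-regulation of
interferon regulatory factor 4 gene expression in leukemic cells."* — with a
`Protein` concept over "interferon regulatory factor 4" and two gold
triggers:

```r
library(trigtag)
doc <- irf4_example()
s <- doc$sentences[[1]]
closest_concept_path(s, 2L)          # token 2 is "regulation"
#> <trig_path> 3 hops: 2 - 3 - 9 - 7

cfg <- trig_config("Gene_expression",
                   features = c("token", "concepts", "shortest_path"),
                   context = "window")
feats <- extract_features(s, cfg)
grep("^(SPDistance|SP_EDGE_PATH|SP_VERTEX_PATH)", feats[[3]], value = TRUE)
#> "SP_EDGE_PATH=NMOD-PMOD-NMOD"
#> "SP_VERTEX_PATH_LEMMA=regulation-of-expression-4"
#> "SPDistance=3"
```

The token "regulation" is three dependency hops from the closest concept
token ("4"), along the path regulation–of–expression–4 with edge labels
NMOD, PMOD, NMOD — exactly the features a trigger model conditions on.

Training and evaluating on a generated toy corpus:

```r
corp <- generate_corpus(fixture_spec(n_documents = 20, seed = 42))
parts <- split_corpus(corp, ratio = 0.75, seed = 1)
model <- crf_train(parts$train,
                   trig_config("Gene_expression",
                               features = c("token", "concepts"),
                               context = "window"))
model
#> <trig_crf> Gene_expression (order 1): 473 features, 3 labels, 120 sentences, 39 gold spans

pred <- annotate_corpus(list(model), strip_triggers(parts$dev))
trigger_eval(parts$dev, pred)
#> Exact-match micro-averaged evaluation (0-100)
#>   type                                P        R       F1
#>   Gene_expression                100.00   100.00   100.00
#>   Positive_regulation              0.00     0.00     0.00
#>   [simple]                       100.00   100.00   100.00
#>   [regulation]                     0.00     0.00     0.00
#>   [total]                        100.00    54.17    70.27
```

The single `Gene_expression` model recovers its own type's triggers
perfectly on held-out documents; `Positive_regulation` spans count as
misses until a second model is trained for them (`optimize_triggers()` +
`finalize_models()` automate this per type).

A shell interface over the same functions lives in
`inst/scripts/trigtag.R` (`optimize`, `train`, `annotate`, `evaluate`,
`fixtures` subcommands, one YAML run configuration).

Corpus-scale benchmark figures on the BioNLP shared-task data require the
externally distributed corpus and long optimization runs;
`benchmark_bionlp()` is the documented harness that accepts such a corpus
directory and runs a reduced search space end to end.

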