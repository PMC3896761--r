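# Example run configuration for the trigtag command dispatcher
# (inst/scripts/trigtag.R). One file drives optimize, train and annotate;
# paths are resolved relative to the working directory.
corpus_dir: corpus          # <id>.txt/.conll/.a1/.a1t files
types: [Gene_expression, Positive_regulation]
seed: 1
ratio: 0.75
space:
  features: [token, orthographic, morphological, concepts, dependency_edge, shortest_path]
  orders: [1, 2]
  contexts: [none, window, dependency_window, conjunctions]
  ngram_sizes: [[2], [2, 3], [2, 3, 4]]
  hops: [1, 2, 3]
  vertex: [lemma, token, pos, chunk]
out_dir: optimized          # per-type .yml configurations + trials.tsv
models_dir: models          # per-type .crf bundles
output_dir: predictions     # one annotation file per document
format: a1                  # a1 | json | xml
postprocess: true
# dictionaries:
#   - {file: gene_expression.tsv, type: Gene_expression}
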