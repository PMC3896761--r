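# Greedy configuration search: splitting, per-order trials, the forward
# pass and refinement steps, and final-model training.

test_that("document-level splits partition the corpus reproducibly", {
  corp <- small_corpus(n_documents = 12L, seed = 81L)
  p1 <- split_corpus(corp, 0.75, seed = 13L)
  expect_length(p1$train, 9L)
  expect_length(p1$dev, 3L)
  p2 <- split_corpus(corp, 0.75, seed = 13L)
  expect_equal(vapply(p2$train, function(d) d$id, character(1)),
               vapply(p1$train, function(d) d$id, character(1)))
  p3 <- split_corpus(corp, 0.75, seed = 14L)
  expect_false(identical(vapply(p3$train, function(d) d$id, character(1)),
                         vapply(p1$train, function(d) d$id, character(1))))
  ids <- function(part) sort(vapply(part, function(d) d$id, character(1)))
  expect_equal(sort(c(ids(p1$train), ids(p1$dev))), ids(corp))
  expect_length(intersect(ids(p1$train), ids(p1$dev)), 0L)
  expect_error(split_corpus(corpus(unclass(corp)[1]), 0.75, 1L), "2 documents")
})

test_that("train_models returns the best order and a recomputable F1", {
  corp <- small_corpus(n_documents = 10L, sentences_per_doc = 5L, seed = 82L)
  parts <- split_corpus(corp, 0.7, seed = 3L)
  cfg <- trig_config("Gene_expression", features = c("token", "concepts"),
                     context = "window")
  tm1 <- train_models(parts$train, parts$dev, cfg, orders = 1L)
  expect_equal(tm1$best_order, 1L)
  expect_length(tm1$f1_by_order, 1L)
  tm <- train_models(parts$train, parts$dev, cfg, orders = c(1L, 2L))
  expect_equal(tm$best_f1, max(tm$f1_by_order))
  # recount oracle: recompute micro-F1 from the stored dev predictions
  mat <- match_exact(list(), list())
  for (d in parts$dev)
    mat <- trigtag:::combine_matrices(mat, match_exact(
      doc_annotations(d, kind = "trigger", type = "Gene_expression"),
      tm$dev_pred[[d$id]]))
  expect_equal(unname(micro_prf(mat)["F1"]), tm$best_f1)
})

test_that("a single-point space returns the only candidate configuration", {
  corp <- small_corpus(n_documents = 10L, sentences_per_doc = 6L,
                       noise_rate = 0, seed = 83L)
  space <- optimization_space(types = "Gene_expression", features = "token",
                              orders = 1L, contexts = "none",
                              ngram_sizes = list(c(2L, 3L)), hops = 3L,
                              vertex = "lemma")
  opt <- optimize_triggers(corp, space, seed = 5L)
  cfg <- opt$configs$Gene_expression
  expect_equal(cfg$features, "token")
  expect_equal(cfg$context, "none")
  expect_equal(cfg$order, 1L)
})

test_that("the optimizer recovers a token-separable task with monotone accepted F1", {
  # noise 0: every lexicon occurrence is a trigger, so token text suffices
  corp <- small_corpus(n_documents = 14L, sentences_per_doc = 6L,
                       noise_rate = 0, seed = 84L)
  space <- optimization_space(
    types = names(trigtag:::DEFAULT_LEXICONS),
    features = c("token", "orthographic", "concepts"),
    orders = 1L, contexts = c("none", "window"),
    ngram_sizes = list(c(2L, 3L)), hops = 3L, vertex = "lemma")
  opt <- optimize_triggers(corp, space, seed = 7L)
  for (ty in space$types) {
    cfg <- opt$configs[[ty]]
    expect_true("token" %in% cfg$features)
    acc <- opt$log[opt$log$type == ty & opt$log$accepted, ]
    expect_gte(nrow(acc), 1L)
    expect_true(all(diff(acc$best_f1) >= 0))      # monotone accepted sequence
    expect_gte(max(acc$best_f1), 95)
    # subset validity
    expect_true(all(cfg$features %in% space$features))
    expect_true(cfg$context %in% space$contexts)
    expect_true(cfg$order %in% space$orders)
  }
  # skipping: families rejected in the forward pass never reach refinement
  rejected <- opt$log[opt$log$step == "feature" & !opt$log$accepted, ]
  later <- opt$log[grepl("^(ngram|hops|vertex):", opt$log$step), ]
  for (k in seq_len(nrow(rejected))) {
    fam <- rejected$candidate[k]
    expect_false(any(later$type == rejected$type[k] &
                       grepl(paste0(":", fam, "$"), later$step)))
  }
})

test_that("optimization is bit-reproducible under a fixed seed", {
  corp <- small_corpus(n_documents = 8L, sentences_per_doc = 4L, seed = 85L)
  space <- optimization_space(types = "Gene_expression",
                              features = c("token", "concepts"),
                              orders = 1L, contexts = c("none", "window"),
                              ngram_sizes = list(c(2L, 3L)), hops = 3L,
                              vertex = "lemma")
  o1 <- optimize_triggers(corp, space, seed = 9L)
  o2 <- optimize_triggers(corp, space, seed = 9L)
  expect_identical(o1$configs, o2$configs)
  expect_identical(o1$log, o2$log)
})

test_that("a type without gold spans is skipped with a warning", {
  corp <- small_corpus(n_documents = 6L, sentences_per_doc = 4L, seed = 86L)
  space <- optimization_space(types = c("Gene_expression", "Binding"),
                              features = "token", orders = 1L,
                              contexts = "none",
                              ngram_sizes = list(2L), hops = 1L,
                              vertex = "lemma")
  expect_warning(opt <- optimize_triggers(corp, space, seed = 3L), "Binding")
  expect_named(opt$configs, "Gene_expression")
})

test_that("finalized models persist, reload and hold up on the dev split", {
  corp <- small_corpus(n_documents = 12L, sentences_per_doc = 5L, seed = 87L)
  space <- optimization_space(types = names(trigtag:::DEFAULT_LEXICONS),
                              features = c("token", "concepts"),
                              orders = 1L, contexts = c("none", "window"),
                              ngram_sizes = list(c(2L, 3L)), hops = 3L,
                              vertex = "lemma")
  opt <- optimize_triggers(corp, space, seed = 11L)
  dir <- withr_tempdir()
  models <- finalize_models(corp, opt$configs, models_dir = dir)
  expect_length(models, 2L)
  expect_setequal(list.files(dir), paste0(names(opt$configs), ".crf"))
  parts <- split_corpus(corp, 0.75, seed = 11L)
  for (ty in names(models)) {
    m2 <- load_model(file.path(dir, paste0(ty, ".crf")))
    expect_equal(ann_span_keys(predict(m2, parts$dev[[1]])),
                 ann_span_keys(predict(models[[ty]], parts$dev[[1]])))
    acc <- opt$log[opt$log$type == ty & opt$log$accepted, ]
    final_f1 <- trigtag:::dev_f1(models[[ty]], parts$dev, list())
    expect_gte(final_f1, max(acc$best_f1) - 5)   # more data: no real regression
  }
})
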