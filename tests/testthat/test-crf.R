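# BIO encoding, the composite-label order reduction, CRF training and
# decoding, and multi-model annotation with shared extraction.

test_that("BIO encoding marks trigger spans and round-trips through decoding", {
  s <- example_sentence()
  lab <- encode_bio(s, "Negative_regulation")
  expect_equal(lab[1:4], c("B", "I", "I", "O"))   # "Down-regulation" = 3 tokens
  expect_equal(encode_bio(s, "Phosphorylation"), rep("O", 14L))
  back <- trigtag:::decode_bio(encode_bio(s, "Gene_expression"), s,
                               "Gene_expression")
  expect_length(back, 1L)
  expect_equal(back[[1]]$text, "expression")
  # round trip over a generated corpus
  corp <- small_corpus(n_documents = 4L, seed = 51L)
  for (d in corp) for (sn in d$sentences) {
    for (ty in names(trigtag:::DEFAULT_LEXICONS)) {
      gold <- tree_annotations(sn$annotations, kind = "trigger", type = ty)
      dec <- trigtag:::decode_bio(encode_bio(sn, ty), sn, ty)
      expect_equal(ann_span_keys(dec), ann_span_keys(gold))
    }
  }
  # misaligned span is an alignment error naming the annotation
  bad <- s
  bad$annotations <- insert_annotation(bad$annotations, annotation(
    "T9", "Binding", 1L, 3L, "ow", kind = "trigger"))
  expect_error(encode_bio(bad, "Binding"), "T9")
})

test_that("raise_order builds composite labels and lower_order inverts it", {
  expect_equal(raise_order(c("B", "I", "O"), 1L), c("B", "I", "O"))
  expect_equal(raise_order(c("B", "I", "O"), 2L), c("B", "B|I", "I|O"))
  expect_error(raise_order(c("B"), 0L), "order")
  trigtag:::with_seed(19L, {
    for (k in 1:10) {
      y <- sample(c("O", "B", "I"), sample(1:9, 1L), TRUE)
      for (o in 1:3)
        expect_equal(lower_order(raise_order(y, o)), y)
    }
  })
})

test_that("training recovers a synthetic tagging task and is deterministic", {
  corp <- small_corpus(n_documents = 16L, sentences_per_doc = 8L,
                       noise_rate = 0.2, seed = 61L)
  parts <- split_corpus(corp, 0.75, seed = 2L)
  cfg <- trig_config("Gene_expression", features = c("token", "concepts"),
                     context = "window")
  m1 <- crf_train(parts$train, cfg)
  m2 <- crf_train(parts$train, cfg)
  expect_identical(m1$weights, m2$weights)
  f1 <- trigtag:::dev_f1(m1, parts$dev, list())
  expect_gte(f1, 95)
  # a corpus without positive spans trains with a degenerate-model warning
  bare <- strip_triggers(corpus(unclass(corp)[1:2]))
  expect_warning(crf_train(bare, cfg), "degenerate")
})

test_that("higher order is no worse than first order beyond noise tolerance", {
  corp <- small_corpus(n_documents = 24L, sentences_per_doc = 8L,
                       noise_rate = 0.2, seed = 62L)
  parts <- split_corpus(corp, 0.75, seed = 2L)
  cfg1 <- trig_config("Gene_expression", features = c("token", "concepts"),
                      context = "window", order = 1L)
  cfg3 <- cfg1; cfg3$order <- 3L
  f1_1 <- trigtag:::dev_f1(crf_train(parts$train, cfg1), parts$dev, list())
  f1_3 <- trigtag:::dev_f1(crf_train(parts$train, cfg3), parts$dev, list())
  expect_gte(f1_3, f1_1 - 5)
})

test_that("Viterbi scores equal exhaustive enumeration on short sentences", {
  corp <- small_corpus(n_documents = 6L, sentences_per_doc = 5L, seed = 63L)
  for (order in c(1L, 2L)) {
    cfg <- trig_config("Gene_expression", features = "token", order = order)
    m <- crf_train(corp, cfg)
    # short sentences keep the enumeration exhaustive yet tractable
    n_max <- if (order == 1L) 6L else 4L
    for (seed in 1:4) {
      s <- random_parsed_sentence(sample(2:n_max, 1L), seed + 70L)
      inst <- extract_features(s, cfg)
      ids <- model_feat_ids(m, inst)
      vit <- trigtag:::crf_viterbi(m$weights, ids, length(m$feat_alpha),
                                   length(m$label_alpha), m$masks$trans_ok,
                                   m$masks$init_ok)
      expect_equal(vit$score, enumeration_best_score(m, ids), tolerance = 1e-9)
      expect_equal(r_path_score(m, ids, vit$path), vit$score,
                   tolerance = 1e-9)
    }
  }
})

test_that("decoding converts label runs to spans, including boundary cases", {
  s <- example_sentence()
  expect_length(trigtag:::decode_bio(rep("O", 14L), s, "X"), 0L)
  lab <- c(rep("O", 13L), "B")                    # B at the final token
  dec <- trigtag:::decode_bio(lab, s, "X")
  expect_length(dec, 1L)
  expect_equal(dec[[1]]$end, s$end)
  # "I" directly after "O" opens a new span
  lab2 <- c("O", "I", rep("O", 12L))
  expect_length(trigtag:::decode_bio(lab2, s, "X"), 1L)
})

test_that("predictions are insensitive to feature-string order within tokens", {
  corp <- small_corpus(n_documents = 6L, seed = 64L)
  cfg <- trig_config("Gene_expression", features = c("token", "orthographic"))
  m <- crf_train(corp, cfg)
  s <- corp[[1]]$sentences[[1]]
  inst <- extract_features(s, cfg)
  shuffled <- trigtag:::with_seed(3L, lapply(inst, sample))
  expect_equal(ann_span_keys(trigtag:::decode_sentence(m, s, inst)),
               ann_span_keys(trigtag:::decode_sentence(m, s, shuffled)))
})

test_that("multi-model annotation via union extraction equals per-model decoding", {
  corp <- small_corpus(n_documents = 10L, sentences_per_doc = 5L, seed = 65L)
  parts <- split_corpus(corp, 0.6, seed = 4L)
  cfgs <- list(
    trig_config("Gene_expression", features = c("token", "concepts"),
                context = "window"),
    trig_config("Positive_regulation", features = c("token", "orthographic"),
                context = "conjunctions"))
  models <- lapply(cfgs, function(c_) crf_train(parts$train, c_))
  # union-path corpus annotation
  ann <- annotate_corpus(models, strip_triggers(parts$dev),
                         postprocess = FALSE)
  union_pred <- unlist(lapply(ann, function(d)
    ann_span_keys(doc_annotations(d, kind = "trigger"))))
  # per-model full-extraction predictions
  direct_pred <- character(0)
  for (m in models) for (d in strip_triggers(parts$dev))
    direct_pred <- c(direct_pred, ann_span_keys(predict(m, d)))
  expect_setequal(union_pred, direct_pred)
  # zero models leave the corpus unchanged
  expect_identical(annotate_corpus(list(), parts$dev), parts$dev)
})

test_that("per-type models never suppress another type's spans", {
  corp <- small_corpus(n_documents = 10L, sentences_per_doc = 5L, seed = 66L)
  parts <- split_corpus(corp, 0.6, seed = 4L)
  cfg <- function(ty) trig_config(ty, features = c("token", "concepts"),
                                  context = "window")
  m_ge <- crf_train(parts$train, cfg("Gene_expression"))
  m_pr <- crf_train(parts$train, cfg("Positive_regulation"))
  solo <- annotate_corpus(list(m_ge), strip_triggers(parts$dev))
  both <- annotate_corpus(list(m_ge, m_pr), strip_triggers(parts$dev))
  solo_keys <- unlist(lapply(solo, function(d)
    ann_span_keys(doc_annotations(d, kind = "trigger", type = "Gene_expression"))))
  both_keys <- unlist(lapply(both, function(d)
    ann_span_keys(doc_annotations(d, kind = "trigger", type = "Gene_expression"))))
  expect_setequal(both_keys, solo_keys)
})

test_that("saved model bundles reload with identical predictions", {
  corp <- small_corpus(n_documents = 6L, seed = 67L)
  cfg <- trig_config("Gene_expression", features = c("token", "concepts"),
                     context = "window")
  m <- crf_train(corp, cfg)
  f <- tempfile(fileext = ".crf")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$weights, m$weights)
  for (d in unclass(corp)[1:2])
    expect_equal(ann_span_keys(predict(m2, d)), ann_span_keys(predict(m, d)))
})
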