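# The feature catalogue: per-family extractors, context modes, and the
# union-then-filter machinery for one-pass multi-model extraction.

two_token_np <- function() {
  rows <- data.frame(text = c("gene", "expression"), start = c(0L, 5L),
                     end = c(4L, 15L), lemma = c("gene", "expression"),
                     pos = c("NN", "NN"))
  build_sentence(rows, chunk_tags = c("B-NP", "I-NP"),
                 doc_text = "gene expression")
}

test_that("token features carry text, lemma, POS and BIO chunk tags", {
  s <- two_token_np()
  fs <- trigtag:::token_features(s)
  expect_true("CHUNK=B-NP" %in% fs[[1]])
  expect_true("CHUNK=I-NP" %in% fs[[2]])
  expect_true("LEMMA=expression" %in% fs[[2]])
  for (seed in 1:3) {
    r <- random_parsed_sentence(7L, seed + 40L)
    fr <- trigtag:::token_features(r)
    expect_true(all(vapply(fr, function(v) sum(startsWith(v, "POS=")) == 1L,
                           logical(1))))
  }
})

test_that("orthographic counts equal per-character tallies", {
  mk <- function(w) {
    rows <- data.frame(text = w, start = 0L, end = nchar(w),
                       lemma = tolower(w), pos = "NN")
    build_sentence(rows, doc_text = w)
  }
  f <- trigtag:::orthographic_features(mk("Abc"))[[1]]
  expect_true("CAPS=InitUpp" %in% f)
  expect_true("CAPS=MixCase" %in% f)
  f2 <- trigtag:::orthographic_features(mk("abc"))[[1]]
  expect_true(all(c("COUNT_UPP=0", "COUNT_DIGIT=0", "LENGTH=3") %in% f2))
  trigtag:::with_seed(3L, {
    for (k in 1:10) {
      w <- paste(sample(c(letters, LETTERS, 0:9, ".", ",", "-"),
                        sample(1:12, 1L), TRUE), collapse = "")
      fs <- trigtag:::orthographic_features(mk(w))[[1]]
      ch <- strsplit(w, "")[[1]]
      expect_true(paste0("COUNT_UPP=", sum(grepl("[A-Z]", ch))) %in% fs)
      expect_true(paste0("COUNT_DIGIT=", sum(grepl("[0-9]", ch))) %in% fs)
      expect_true(paste0("LENGTH=", length(ch)) %in% fs)
    }
  })
})

test_that("morphological features emit affixes, char n-grams and word shape", {
  mk <- function(w) {
    rows <- data.frame(text = w, start = 0L, end = nchar(w),
                       lemma = tolower(w), pos = "NN")
    build_sentence(rows, doc_text = w)
  }
  f <- trigtag:::morphological_features(mk("coexpression"))[[1]]
  expect_true("PREFIX3=coe" %in% f)
  expect_true("SUFFIX4=sion" %in% f)
  f2 <- trigtag:::morphological_features(mk("Abc:1234"))[[1]]
  expect_true("SHAPE=Aaa#1111" %in% f2)
  f3 <- trigtag:::morphological_features(mk("ab"), ngram_sizes = 3L)[[1]]
  expect_length(grep("^CHARNG3=", f3), 0L)      # token shorter than the n-gram
  expect_length(grep("^PREFIX3=", f3), 0L)      # and than the affix
})

test_that("sentence-length bins are lower-inclusive and number exactly seven", {
  bins <- vapply(1:60, trigtag:::sentence_length_bin, character(1))
  expect_length(unique(bins), 7L)
  expect_equal(trigtag:::sentence_length_bin(11L), "<15")
  expect_equal(trigtag:::sentence_length_bin(15L), "[15,20)")
  s <- example_sentence()
  expect_true("SENT_LEN=<15" %in% trigtag:::sentence_length_features(s)[[1]])
})

test_that("concept features broadcast names, heads and per-type counts", {
  s <- example_sentence()
  fs <- trigtag:::concept_features(s)
  for (i in seq_len(n_tokens(s))) {
    expect_true("CONCEPT_NAME=interferon_regulatory_factor_4" %in% fs[[i]])
    expect_true("CONCEPT_PROTEIN_HEAD=interferon" %in% fs[[i]])
    expect_true("NUM_PROTEIN=1" %in% fs[[i]])
  }
  expect_true("Concept=Protein" %in% fs[[5]])    # a token inside the span
  expect_false("Concept=Protein" %in% fs[[1]])
  # two proteins + one chemical
  r <- random_parsed_sentence(6L, 77L)
  tk <- r$tokens
  for (spec in list(c(0L, "Protein"), c(2L, "Protein"), c(4L, "Chemical"))) {
    i <- as.integer(spec[1])
    r$annotations <- insert_annotation(r$annotations, annotation(
      paste0("T", i), spec[2], tk$start[i + 1L], tk$end[i + 1L],
      tk$text[i + 1L], kind = "concept"))
  }
  fr <- trigtag:::concept_features(r)
  expect_true(all(c("NUM_PROTEIN=2", "NUM_CHEMICAL=1") %in% fr[[1]]))
  plain <- random_parsed_sentence(4L, 78L)
  expect_true(all(lengths(trigtag:::concept_features(plain)) == 0L))
})

test_that("dictionary matches become Trigger features on covered tokens", {
  s <- example_sentence()
  d <- structure(list(entries = list(GE1 = "expression"),
                      event_type = "Gene_expression"),
                 class = "trig_dictionary")
  fs <- trigtag:::dictionary_features(s, list(d))
  expect_true("Trigger=Gene_expression" %in% fs[[10]])   # "expression"
  expect_false("Trigger=Gene_expression" %in% fs[[1]])
  expect_true(all(lengths(trigtag:::dictionary_features(s, list())) == 0L))
})

test_that("modifier features read roles off directed edges", {
  rows <- data.frame(text = c("cells", "express", "IL2"),
                     start = c(0L, 6L, 14L), end = c(5L, 13L, 17L),
                     lemma = c("cell", "express", "il2"),
                     pos = c("NNS", "VBP", "NN"))
  edges <- data.frame(head = c(1L, 1L), dep = c(0L, 2L),
                      label = c("SUB", "OBJ"))
  s <- build_sentence(rows, dep_edges = edges,
                      chunk_tags = c("B-NP", "B-VP", "B-NP"),
                      doc_text = "cells express IL2")
  fs <- trigtag:::modifier_features(s)
  expect_true("SUBJ_OF_VERB=express" %in% fs[[1]])
  expect_true("OBJ_OF_VERB=express" %in% fs[[3]])
  expect_true(all(c("MODIFIER=cell", "MODIFIER=il2") %in% fs[[2]]))
  # exhaustive edge-scan oracle on random parses
  for (seed in 1:4) {
    r <- random_parsed_sentence(8L, seed + 500L)
    fr <- trigtag:::modifier_features(r)
    for (rr in seq_len(nrow(r$edges))) {
      h <- r$edges$head[rr]; d <- r$edges$dep[rr]; lab <- r$edges$label[rr]
      expect_true(paste0("MODIFIER=", trigtag:::tok_lemma(r, d)) %in% fr[[h + 1L]])
      if (lab == "SUB" && startsWith(trigtag:::tok_pos(r, h), "V"))
        expect_true(paste0("SUBJ_OF_VERB=", trigtag:::tok_lemma(r, h)) %in% fr[[d + 1L]])
    }
  }
  lone <- random_parsed_sentence(1L, 501L)
  expect_true(all(lengths(trigtag:::modifier_features(lone)) == 0L))
})

test_that("in/out dependency features describe the opposite endpoint", {
  s <- example_sentence()
  fs <- trigtag:::dependency_edge_features(s)
  reg <- fs[[3]]
  expect_true(all(c("IN_DEP_LABEL=NMOD", "IN_DEP_LEMMA=in",
                    "IN_DEP_POS=PP", "IN_DEP_CHUNK=PP") %in% reg))
  expect_true(all(c("OUT_DEP_LABEL=OBJ", "OUT_DEP_LEMMA=−",
                    "OUT_DEP_POS=HYPH", "OUT_DEP_CHUNK=O") %in% reg))
  lone <- random_parsed_sentence(1L, 502L)
  expect_true(all(lengths(trigtag:::dependency_edge_features(lone)) == 0L))
})

test_that("path features join labels and vertex values with n-gram guards", {
  s <- example_sentence()
  p <- closest_concept_path(s, 2L)
  fs <- path_features(p, s, vertex_feature = "lemma", ngram_sizes = 2L)
  expect_true("SP_EDGE_PATH=NMOD-PMOD-NMOD" %in% fs)
  expect_true("SP_EDGE_TYPE=NMOD_3" %in% fs)
  expect_true("SP_VERTEX_PATH_LEMMA=regulation-of-expression-4" %in% fs)
  expect_setequal(grep("^SP_EDGE_NG2=", fs, value = TRUE),
                  c("SP_EDGE_NG2=NMOD_PMOD", "SP_EDGE_NG2=PMOD_NMOD"))
  expect_setequal(grep("^SP_VERTEX_NG2_LEMMA=", fs, value = TRUE),
                  paste0("SP_VERTEX_NG2_LEMMA=",
                         c("regulation_of", "of_expression", "expression_4")))
  one_hop <- shortest_path(s, 2L, 3L)
  fs1 <- path_features(one_hop, s, "lemma", 2L)
  expect_length(grep("_NG", fs1), 0L)            # single edge: no n-grams
  expect_length(path_features(shortest_path(s, 4L, 4L), s), 0L)
})

test_that("shortest-path features respect the hop limit", {
  s <- example_sentence()
  fs3 <- trigtag:::shortest_path_features(s, hop_limit = 3L)
  expect_true("SPDistance=3" %in% fs3[[3]])
  expect_true("SPDistance=0" %in% fs3[[6]])      # token inside the concept
  fs2 <- trigtag:::shortest_path_features(s, hop_limit = 2L)
  expect_length(fs2[[3]], 0L)                    # 3 hops > limit 2
})

test_that("conjunction and window context follow the fixed offset windows", {
  s <- example_sentence()
  conj <- trigtag:::apply_conjunctions(s)
  expect_true("CONJ_LEMMA_-1_1=interferon@-1_&_factor@1" %in% conj[[6]])
  expect_length(grep("CONJ_LEMMA_-1_0", conj[[1]]), 0L)  # out of range at start
  win <- trigtag:::apply_local_windows(s)
  mid <- win[[6]]
  expect_true("WIN_LEMMA@-1=interferon" %in% mid)
  expect_true("WIN_LEMMA@1=factor" %in% mid)
  rows <- data.frame(text = "x", start = 0L, end = 1L, lemma = "x", pos = "NN")
  single <- build_sentence(rows, doc_text = "x")
  expect_true(all(lengths(trigtag:::apply_local_windows(single)) == 0L))
  # enumeration oracle on the counts
  for (seed in 1:3) {
    r <- random_parsed_sentence(6L, seed + 600L)
    cr <- trigtag:::apply_conjunctions(r)
    for (i in seq_len(6L)) {
      n_ok <- sum(vapply(trigtag:::CONTEXT_WINDOWS, function(w)
        all(i + w >= 1L & i + w <= 6L), logical(1)))
      expect_length(cr[[i]], 2L * n_ok)          # lemma and POS streams
    }
  }
})

test_that("dependency windows copy features of tokens within k hops", {
  s <- example_sentence()
  dw <- trigtag:::apply_dependency_windows(s, max_hops = 1L)
  lem <- sub("^DW1_LEMMA=", "", grep("^DW1_LEMMA=", dw[[3]], value = TRUE))
  expect_setequal(lem, c("of", "−", "in"))
  lone <- random_parsed_sentence(1L, 700L)
  expect_true(all(lengths(trigtag:::apply_dependency_windows(lone, 2L)) == 0L))
  for (seed in 1:3) {
    r <- random_parsed_sentence(9L, seed + 800L)
    dwr <- trigtag:::apply_dependency_windows(r, max_hops = 2L)
    for (i in c(1L, 5L)) {
      dist <- bfs_oracle(9L, r$edges, i - 1L)
      expected <- sum(!is.na(dist) & dist >= 1L & dist <= 2L) * 3L
      expect_length(dwr[[i]], expected)
    }
  }
})

test_that("extract_features honors the family switches", {
  s <- example_sentence()
  only_tok <- extract_features(s, trig_config("X", features = "token"))
  expect_length(grep("^(CAPS|SP_|IN_DEP)", unlist(only_tok)), 0L)
  expect_true("W=regulation" %in% only_tok[[3]])
  expect_error(trig_config("X", features = "embeddings"), "unknown feature family")
  # determinism: byte-identical repeated extraction
  full <- trig_config("X", features = trigtag:::FEATURE_FAMILIES,
                      context = "conjunctions")
  d <- structure(list(entries = list(a = "expression"), event_type = "GE"),
                 class = "trig_dictionary")
  expect_identical(extract_features(s, full, list(d)),
                   extract_features(s, full, list(d)))
})

test_that("filtering a union extraction equals direct per-config extraction", {
  d <- structure(list(entries = list(a = c("expression", "factor")),
                      event_type = "GE"), class = "trig_dictionary")
  configs <- list(
    trig_config("A", features = "token"),
    trig_config("B", features = c("token", "orthographic"),
                context = "window"),
    trig_config("C", features = c("morphological", "shortest_path"),
                ngram_sizes = list(morphological = 2L, shortest_path = 2L),
                hops = list(shortest_path = 2L, dependency_window = 3L),
                vertex = list(shortest_path = "pos"), order = 2L),
    trig_config("D", features = c("concepts", "dictionary", "modifier",
                                  "dependency_edge", "shortest_path"),
                context = "dependency_window",
                hops = list(shortest_path = 3L, dependency_window = 1L)))
  uni <- union_configs(configs)
  expect_setequal(uni$features,
                  unique(unlist(lapply(configs, function(c) c$features))))
  sentences <- c(list(example_sentence()),
                 lapply(1:30, function(k)
                   random_parsed_sentence(sample(3:9, 1L), k + 900L,
                                          with_concept = TRUE)))
  for (s in sentences) {
    base <- extract_features(s, uni, list(d))
    for (cfg in configs)
      expect_identical(filter_features(base, s, cfg),
                       extract_features(s, cfg, list(d)))
  }
})
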