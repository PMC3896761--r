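# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (exhaustive enumeration, brute-force scans)
# and independent of the package's implementation paths.

example_sentence <- function() irf4_example()$sentences[[1]]

# random sentence with a random labeled tree parse; deterministic per seed
random_parsed_sentence <- function(n, seed, with_concept = FALSE) {
  trigtag:::with_seed(seed, {
    words <- replicate(n, paste(sample(letters, sample(2:8, 1), TRUE),
                                collapse = ""))
    starts <- cumsum(c(0L, head(nchar(words), -1L) + 1L))
    ends <- starts + nchar(words)
    text <- paste(words, collapse = " ")
    pos <- sample(c("NN", "NNS", "VBD", "VBZ", "JJ", "PP", "CD"), n, TRUE)
    chunk <- ifelse(runif(n) < 0.3, "O", "B-NP")
    edges <- NULL
    if (n > 1L) {
      heads <- vapply(2:n, function(i) sample(seq_len(i - 1L), 1L), integer(1))
      edges <- data.frame(head = heads - 1L, dep = 1:(n - 1L),
                          label = sample(c("SUB", "OBJ", "NMOD", "PMOD", "VMOD"),
                                         n - 1L, TRUE),
                          stringsAsFactors = FALSE)
    }
    rows <- data.frame(text = words, start = starts, end = ends,
                       lemma = tolower(words), pos = pos,
                       stringsAsFactors = FALSE)
    s <- build_sentence(rows, dep_edges = edges, chunk_tags = chunk,
                        doc_text = text)
    if (with_concept && n >= 2L) {
      i <- sample(seq_len(n), 1L)
      s$annotations <- insert_annotation(s$annotations, annotation(
        "T1", "Protein", starts[i], ends[i], words[i], kind = "concept"))
    }
    s
  })
}

# independent BFS distances over an explicit edge list (0-based vertices)
bfs_oracle <- function(n, edges, from) {
  dist <- rep(NA_integer_, n)
  dist[from + 1L] <- 0L
  repeat {
    changed <- FALSE
    if (nrow(edges)) for (r in seq_len(nrow(edges))) {
      a <- edges$head[r] + 1L; b <- edges$dep[r] + 1L
      if (!is.na(dist[a]) && (is.na(dist[b]) || dist[b] > dist[a] + 1L)) {
        dist[b] <- dist[a] + 1L; changed <- TRUE
      }
      if (!is.na(dist[b]) && (is.na(dist[a]) || dist[a] > dist[b] + 1L)) {
        dist[a] <- dist[b] + 1L; changed <- TRUE
      }
    }
    if (!changed) break
  }
  dist
}

# unnormalized log score of a label path, recomputed in R from the model's
# parameter layout (independent of the C++ scorer)
r_path_score <- function(model, feat_ids, label_ids) {
  L <- length(model$label_alpha)
  n_state <- length(model$feat_alpha) * L
  w <- model$weights
  sc <- 0
  for (t in seq_along(feat_ids)) {
    l <- label_ids[t]
    for (f in feat_ids[[t]]) sc <- sc + w[(f - 1L) * L + l]
    if (t > 1L) sc <- sc + w[n_state + (label_ids[t - 1L] - 1L) * L + l]
  }
  sc
}

# exhaustive max over all mask-legal label sequences
enumeration_best_score <- function(model, feat_ids) {
  L <- length(model$label_alpha)
  T_ <- length(feat_ids)
  grids <- expand.grid(rep(list(seq_len(L)), T_))
  best <- -Inf
  for (r in seq_len(nrow(grids))) {
    y <- as.integer(grids[r, ])
    if (!model$masks$init_ok[y[1L]]) next
    ok <- TRUE
    if (T_ > 1L) for (t in 2:T_)
      if (!model$masks$trans_ok[y[t - 1L], y[t]]) { ok <- FALSE; break }
    if (!ok) next
    sc <- r_path_score(model, feat_ids, y)
    if (sc > best) best <- sc
  }
  best
}

# feature ids of a sentence instance under a model's alphabet (bias included)
model_feat_ids <- function(model, instance) {
  idx <- setNames(seq_along(model$feat_alpha), model$feat_alpha)
  lapply(instance, function(strs) {
    ids <- idx[strs]
    c(1L, sort(unname(ids[!is.na(ids)])))
  })
}

# brute-force case-folded substring scan with token-boundary alignment and
# longest-match preference, mirroring the matcher's contract
naive_dictionary_scan <- function(patterns, sentence) {
  text <- tolower(sentence$text)
  nst <- nchar(text)
  hits <- list()
  for (p in tolower(patterns)) {
    np <- nchar(p)
    if (np > nst) next
    for (i in seq_len(nst - np + 1L)) {
      if (substr(text, i, i + np - 1L) == p) {
        s <- sentence$start + i - 1L; e <- s + np
        if (s %in% sentence$tokens$start && e %in% sentence$tokens$end)
          hits[[length(hits) + 1L]] <- c(s, e)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2L))
  hm <- unique(do.call(rbind, hits))
  keep <- rep(TRUE, nrow(hm))
  for (i in seq_len(nrow(hm))) for (j in seq_len(nrow(hm)))
    if (i != j && hm[j, 1] <= hm[i, 1] && hm[i, 2] <= hm[j, 2] &&
        (hm[j, 2] - hm[j, 1]) > (hm[i, 2] - hm[i, 1])) keep[i] <- FALSE
  hm <- hm[keep, , drop = FALSE]
  hm[order(hm[, 1], hm[, 2]), , drop = FALSE]
}

ann_span_keys <- function(anns)
  sort(vapply(anns, function(a) paste(a$type, a$start, a$end), character(1)))

withr_tempdir <- function() {
  d <- tempfile("trigtag")
  dir.create(d)
  d
}

small_corpus <- function(n_documents = 12L, sentences_per_doc = 6L,
                         noise_rate = 0.2, seed = 11L)
  generate_corpus(fixture_spec(n_documents = n_documents,
                               sentences_per_doc = sentences_per_doc,
                               noise_rate = noise_rate, seed = seed))
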