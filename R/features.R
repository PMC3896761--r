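# The feature catalogue. Every feature is a categorical "KEY=value" string;
# parameters that vary under optimization (n-gram size, dependency hops,
# vertex information) are encoded in the KEY so that a superset extraction
# can be filtered down to any member configuration without re-extraction.

FEATURE_FAMILIES <- c("token", "orthographic", "morphological",
                      "sentence_length", "concepts", "dictionary",
                      "modifier", "dependency_edge", "shortest_path")
CONTEXT_MODES <- c("none", "window", "dependency_window", "conjunctions")
VERTEX_TYPES <- c("lemma", "token", "pos", "chunk")
NGRAM_FAMILIES <- c("morphological", "shortest_path")
HOP_FAMILIES <- c("shortest_path")
VERTEX_FAMILIES <- c("shortest_path")

#' Model configuration for one event type
#'
#' Records which feature families a trigger model uses, its local-context
#' mode, per-family n-gram sizes, dependency-hop limits, the token
#' information used on path vertices, and the CRF model order. This is the
#' unit the greedy optimizer searches over.
#'
#' @param event_type Trigger type the model targets (e.g. `"Gene_expression"`).
#' @param features Character vector of active feature families, a subset of
#'   `token`, `orthographic`, `morphological`, `sentence_length`, `concepts`,
#'   `dictionary`, `modifier`, `dependency_edge`, `shortest_path`.
#' @param context One of `"none"`, `"window"`, `"dependency_window"`,
#'   `"conjunctions"`.
#' @param ngram_sizes Named list (families `morphological`, `shortest_path`)
#'   of integer vectors of n-gram sizes, each size >= 2.
#' @param hops Named list of max dependency hops (>= 1): key `shortest_path`
#'   bounds token-to-concept paths; key `dependency_window` (<= 3) bounds the
#'   dependency-window context.
#' @param vertex Named list mapping `shortest_path` to the vertex information
#'   used in path features: `"lemma"`, `"token"`, `"pos"` or `"chunk"`
#'   (several values allowed only in superset configurations).
#' @param order CRF model order (>= 1); each label conditions on the
#'   `order - 1` previous labels.
#' @return An object of class `trig_config`.
#' @export
trig_config <- function(event_type,
                        features = c("token"),
                        context = "none",
                        ngram_sizes = list(morphological = c(2L, 3L),
                                           shortest_path = c(2L, 3L)),
                        hops = list(shortest_path = 3L, dependency_window = 3L),
                        vertex = list(shortest_path = "lemma"),
                        order = 1L) {
  features <- unique(as.character(features))
  bad <- setdiff(features, FEATURE_FAMILIES)
  if (length(bad)) stop("unknown feature family: ", paste(bad, collapse = ", "))
  if (!context %in% CONTEXT_MODES)
    stop("unknown context mode \"", context, "\"")
  for (fam in names(ngram_sizes)) {
    if (!fam %in% NGRAM_FAMILIES)
      stop("family \"", fam, "\" does not take n-gram sizes")
    if (any(ngram_sizes[[fam]] < 2L)) stop("n-gram sizes must be >= 2")
  }
  for (fam in names(hops)) {
    if (!fam %in% c(HOP_FAMILIES, "dependency_window"))
      stop("family \"", fam, "\" does not take a hop limit")
    if (hops[[fam]] < 1L) stop("hop limits must be >= 1")
  }
  for (fam in names(vertex)) {
    if (!fam %in% VERTEX_FAMILIES)
      stop("family \"", fam, "\" does not take a vertex feature type")
    if (!all(vertex[[fam]] %in% VERTEX_TYPES))
      stop("vertex feature must be one of ", paste(VERTEX_TYPES, collapse = ", "))
  }
  if (!is.numeric(order) || order < 1L) stop("model order must be >= 1")
  structure(list(event_type = as.character(event_type), features = features,
                 context = context,
                 ngram_sizes = lapply(ngram_sizes, as.integer),
                 hops = lapply(hops, as.integer), vertex = vertex,
                 order = as.integer(order)),
            class = "trig_config")
}

#' @export
print.trig_config <- function(x, ...) {
  cat("<trig_config> ", x$event_type, " (order ", x$order, ")\n", sep = "")
  cat("  families: ", if (length(x$features)) paste(x$features, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  context:  ", x$context, "\n", sep = "")
  for (fam in names(x$ngram_sizes))
    cat("  n-grams[", fam, "]: {", paste(x$ngram_sizes[[fam]], collapse = ","),
        "}\n", sep = "")
  for (fam in names(x$hops))
    cat("  hops[", fam, "]: ", x$hops[[fam]], "\n", sep = "")
  for (fam in names(x$vertex))
    cat("  vertex[", fam, "]: ", paste(x$vertex[[fam]], collapse = ","),
        "\n", sep = "")
  invisible(x)
}

kv <- function(key, value) paste0(key, "=", value)

## ---- per-family extractors (each returns a list of per-token string vectors)

token_features <- function(sentence) {
  n <- n_tokens(sentence)
  bio <- chunk_bio_tags(sentence)
  warned <- FALSE
  lapply(seq_len(n), function(i) {
    out <- kv("W", sentence$tokens$text[i])
    lem <- tok_feat1(sentence, i - 1L, "LEMMA")
    pos <- tok_feat1(sentence, i - 1L, "POS")
    if (is.na(lem) || is.na(pos)) {
      if (!warned) { warned <<- TRUE
        trig_log("token ", i - 1L, " lacks lemma/POS; emitting text only") }
    }
    if (!is.na(lem)) out <- c(out, kv("LEMMA", lem))
    if (!is.na(pos)) out <- c(out, kv("POS", pos))
    c(out, kv("CHUNK", bio[i]))
  })
}

orthographic_features <- function(sentence) {
  symbol_map <- c("." = "Dot", "," = "Comma", ";" = "Semicolon", ":" = "Colon",
                  "-" = "Hyphen", "(" = "OpenRound", ")" = "CloseRound",
                  "[" = "OpenSquare", "]" = "CloseSquare",
                  "{" = "OpenCurly", "}" = "CloseCurly", "/" = "Slash",
                  "%" = "Percent", "+" = "Plus", "=" = "Equals",
                  "*" = "Star", "'" = "Apostrophe", "\"" = "Quote",
                  "&" = "Amp")
  lapply(sentence$tokens$text, function(w) {
    ch <- strsplit(w, "")[[1L]]
    upp <- grepl("[A-Z]", ch); low <- grepl("[a-z]", ch); dig <- grepl("[0-9]", ch)
    out <- character(0)
    if (length(ch) && upp[1L]) out <- c(out, kv("CAPS", "InitUpp"))
    if (any(upp) && !any(low)) out <- c(out, kv("CAPS", "AllUpp"))
    if (any(upp) && any(low)) out <- c(out, kv("CAPS", "MixCase"))
    if (any(low) && !any(upp)) out <- c(out, kv("CAPS", "AllLow"))
    out <- c(out, kv("COUNT_UPP", sum(upp)), kv("COUNT_DIGIT", sum(dig)),
             kv("LENGTH", length(ch)))
    syms <- unique(ch[ch %in% names(symbol_map)])
    c(out, vapply(syms, function(s) kv("SYMBOL", symbol_map[[s]]), character(1)))
  })
}

word_shape <- function(w) {
  ch <- strsplit(w, "")[[1L]]
  paste(ifelse(grepl("[A-Z]", ch), "A",
        ifelse(grepl("[a-z]", ch), "a",
        ifelse(grepl("[0-9]", ch), "1", "#"))), collapse = "")
}

char_ngrams <- function(w, k) {
  n <- nchar(w)
  if (n < k) return(character(0))
  unique(vapply(seq_len(n - k + 1L), function(i) substr(w, i, i + k - 1L),
                character(1)))
}

morphological_features <- function(sentence, ngram_sizes = c(2L, 3L)) {
  lapply(sentence$tokens$text, function(w) {
    n <- nchar(w)
    out <- character(0)
    for (k in 2:4) {
      if (n >= k) {
        out <- c(out, kv(paste0("PREFIX", k), substr(w, 1L, k)),
                 kv(paste0("SUFFIX", k), substr(w, n - k + 1L, n)))
      }
    }
    for (k in ngram_sizes)
      out <- c(out, vapply(char_ngrams(w, k),
                           function(g) kv(paste0("CHARNG", k), g), character(1)))
    c(out, kv("SHAPE", word_shape(w)))
  })
}

sentence_length_bin <- function(n) {
  if (n < 15L) "<15" else if (n < 20L) "[15,20)" else if (n < 25L) "[20,25)"
  else if (n < 30L) "[25,30)" else if (n < 35L) "[30,35)"
  else if (n < 40L) "[35,40)" else ">=40"
}

sentence_length_features <- function(sentence) {
  n <- n_tokens(sentence)
  rep(list(kv("SENT_LEN", sentence_length_bin(n))), n)
}

sanitize_value <- function(x) gsub(" ", "_", x, fixed = TRUE)

concept_features <- function(sentence) {
  n <- n_tokens(sentence)
  anns <- tree_annotations(sentence$annotations, kind = "concept")
  out <- rep(list(character(0)), n)
  if (!length(anns)) return(out)
  tk <- sentence$tokens
  global <- character(0)
  counts <- table(vapply(anns, function(a) a$type, character(1)))
  for (a in anns) {
    covered <- which(tk$start >= a$start & tk$end <= a$end)
    for (i in covered) out[[i]] <- c(out[[i]], kv("Concept", a$type))
    global <- c(global, kv("CONCEPT_NAME", sanitize_value(a$text)))
    if (length(covered))
      global <- c(global, kv(paste0("CONCEPT_", toupper(a$type), "_HEAD"),
                             tk$text[covered[1L]]))
  }
  for (ty in names(counts))
    global <- c(global, kv(paste0("NUM_", toupper(ty)), as.integer(counts[[ty]])))
  lapply(seq_len(n), function(i) c(out[[i]], global))
}

dictionary_features <- function(sentence, dictionaries) {
  n <- n_tokens(sentence)
  out <- rep(list(character(0)), n)
  tk <- sentence$tokens
  for (d in dictionaries) {
    m <- if (inherits(d, "trig_matcher")) d else compile_dictionary(d)
    for (a in match_triggers(m, sentence)) {
      covered <- which(tk$start >= a$start & tk$end <= a$end)
      for (i in covered) out[[i]] <- c(out[[i]], kv("Trigger", a$type))
    }
  }
  lapply(out, unique)
}

is_verb <- function(pos) !is.na(pos) && startsWith(pos, "V")
is_noun <- function(pos) !is.na(pos) && startsWith(pos, "N")

modifier_features <- function(sentence) {
  n <- n_tokens(sentence)
  out <- rep(list(character(0)), n)
  e <- sentence$edges
  if (!nrow(e)) return(out)
  for (r in seq_len(nrow(e))) {
    h <- e$head[r]; d <- e$dep[r]; lab <- e$label[r]
    hpos <- tok_pos(sentence, h)
    # dependent-side roles
    if (startsWith(lab, "SUB") && is_verb(hpos))
      out[[d + 1L]] <- c(out[[d + 1L]], kv("SUBJ_OF_VERB", tok_lemma(sentence, h)))
    if (startsWith(lab, "OBJ") && is_verb(hpos))
      out[[d + 1L]] <- c(out[[d + 1L]], kv("OBJ_OF_VERB", tok_lemma(sentence, h)))
    if (startsWith(lab, "NMOD") && is_noun(hpos))
      out[[d + 1L]] <- c(out[[d + 1L]], kv("MOD_OF_NOUN", tok_lemma(sentence, h)))
    # head side: the dependent is one of this token's modifiers
    out[[h + 1L]] <- c(out[[h + 1L]], kv("MODIFIER", tok_lemma(sentence, d)))
  }
  out
}

dependency_edge_features <- function(sentence) {
  n <- n_tokens(sentence)
  out <- rep(list(character(0)), n)
  e <- sentence$edges
  if (!nrow(e)) return(out)
  other_feats <- function(prefix, j) {
    c(kv(paste0(prefix, "_LEMMA"), tok_lemma(sentence, j)),
      kv(paste0(prefix, "_POS"), tok_pos(sentence, j)),
      kv(paste0(prefix, "_CHUNK"), chunk_label_of(sentence, j)))
  }
  for (r in seq_len(nrow(e))) {
    h <- e$head[r]; d <- e$dep[r]; lab <- e$label[r]
    # the edge is an input dependency of its dependent ...
    out[[d + 1L]] <- c(out[[d + 1L]], kv("IN_DEP_LABEL", lab), other_feats("IN_DEP", h))
    # ... and an output dependency of its head
    out[[h + 1L]] <- c(out[[h + 1L]], kv("OUT_DEP_LABEL", lab), other_feats("OUT_DEP", d))
  }
  out
}

vertex_value <- function(sentence, i, vt) {
  switch(vt,
    lemma = tok_lemma(sentence, i),
    token = sentence$tokens$text[i + 1L],
    pos = { p <- tok_pos(sentence, i); if (is.na(p)) "NA" else p },
    chunk = chunk_label_of(sentence, i),
    stop("unknown vertex feature type \"", vt, "\""))
}

seq_ngrams <- function(values, k, sep = "_") {
  m <- length(values)
  if (m < k) return(character(0))
  vapply(seq_len(m - k + 1L), function(i)
    paste(values[i:(i + k - 1L)], collapse = sep), character(1))
}

#' Features of a dependency path
#'
#' Emits the edge-label path, the edge type (first label + hop count), the
#' vertex path over the chosen token information, and edge/vertex n-grams.
#' A path with fewer than one edge emits nothing; n-grams require at least
#' two edges.
#'
#' @param path A `trig_path`.
#' @param sentence The sentence the path lives in.
#' @param vertex_feature Vertex information: one or more of
#'   `"lemma"`, `"token"`, `"pos"`, `"chunk"`.
#' @param ngram_sizes Integer vector of n-gram sizes (>= 2).
#' @return Character vector of feature strings.
#' @export
path_features <- function(path, sentence, vertex_feature = "lemma",
                          ngram_sizes = c(2L, 3L)) {
  if (is.null(path) || path$hops < 1L) return(character(0))
  out <- c(kv("SP_EDGE_PATH", paste(path$labels, collapse = "-")),
           kv("SP_EDGE_TYPE", paste0(path$labels[1L], "_", path$hops)))
  for (vt in vertex_feature) {
    vv <- vapply(path$vertices, function(i) vertex_value(sentence, i, vt),
                 character(1))
    out <- c(out, kv(paste0("SP_VERTEX_PATH_", toupper(vt)),
                     paste(vv, collapse = "-")))
    if (path$hops >= 2L) {
      for (k in ngram_sizes)
        out <- c(out, vapply(seq_ngrams(vv, k), function(g)
          kv(paste0("SP_VERTEX_NG", k, "_", toupper(vt)), g), character(1)))
    }
  }
  if (path$hops >= 2L) {
    for (k in ngram_sizes)
      out <- c(out, vapply(seq_ngrams(path$labels, k), function(g)
        kv(paste0("SP_EDGE_NG", k), g), character(1)))
  }
  out
}

shortest_path_features <- function(sentence, hop_limit = 3L,
                                   vertex_feature = "lemma",
                                   ngram_sizes = c(2L, 3L)) {
  n <- n_tokens(sentence)
  lapply(seq_len(n) - 1L, function(i) {
    p <- closest_concept_path(sentence, i)
    if (is.null(p) || p$hops > hop_limit) return(character(0))
    c(path_features(p, sentence, vertex_feature, ngram_sizes),
      kv("SPDistance", p$hops))
  })
}

## ---- context ---------------------------------------------------------------

CONTEXT_WINDOWS <- list(c(-3L, -1L), c(-2L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L))

context_stream <- function(sentence, stream) {
  n <- n_tokens(sentence)
  switch(stream,
    W = sentence$tokens$text,
    LEMMA = vapply(seq_len(n) - 1L, function(i) tok_lemma(sentence, i), character(1)),
    POS = vapply(seq_len(n) - 1L, function(i) {
      p <- tok_pos(sentence, i); if (is.na(p)) "NA" else p }, character(1)),
    CHUNK = chunk_bio_tags(sentence),
    stop("unknown stream ", stream))
}

apply_conjunctions <- function(sentence) {
  n <- n_tokens(sentence)
  streams <- list(LEMMA = context_stream(sentence, "LEMMA"),
                  POS = context_stream(sentence, "POS"))
  lapply(seq_len(n), function(i) {
    out <- character(0)
    for (sn in names(streams)) {
      vals <- streams[[sn]]
      for (w in CONTEXT_WINDOWS) {
        pos <- i + w
        if (any(pos < 1L | pos > n)) next
        out <- c(out, kv(paste0("CONJ_", sn, "_", w[1L], "_", w[2L]),
                         paste(paste0(vals[pos], "@", w), collapse = "_&_")))
      }
    }
    out
  })
}

apply_local_windows <- function(sentence) {
  n <- n_tokens(sentence)
  offs <- setdiff(sort(unique(unlist(CONTEXT_WINDOWS))), 0L)
  streams <- list(W = context_stream(sentence, "W"),
                  LEMMA = context_stream(sentence, "LEMMA"),
                  POS = context_stream(sentence, "POS"),
                  CHUNK = context_stream(sentence, "CHUNK"))
  lapply(seq_len(n), function(i) {
    out <- character(0)
    for (o in offs) {
      j <- i + o
      if (j < 1L || j > n) next
      for (sn in names(streams))
        out <- c(out, kv(paste0("WIN_", sn, "@", o), streams[[sn]][j]))
    }
    out
  })
}

apply_dependency_windows <- function(sentence, max_hops = 3L) {
  n <- n_tokens(sentence)
  adj <- adjacency(sentence)
  streams <- list(LEMMA = context_stream(sentence, "LEMMA"),
                  POS = context_stream(sentence, "POS"),
                  CHUNK = context_stream(sentence, "CHUNK"))
  lapply(seq_len(n) - 1L, function(i) {
    dist <- bfs_dist(adj, i)
    out <- character(0)
    for (h in seq_len(max_hops)) {
      nbrs <- which(!is.na(dist) & dist == h) - 1L
      for (j in nbrs)
        for (sn in names(streams))
          out <- c(out, kv(paste0("DW", h, "_", sn), streams[[sn]][j + 1L]))
    }
    out
  })
}

## ---- extraction, union and filtering ---------------------------------------

merge_token_lists <- function(a, b) {
  if (is.null(a)) return(b)
  mapply(c, a, b, SIMPLIFY = FALSE)
}

extract_base <- function(sentence, config, dictionaries = list()) {
  out <- rep(list(character(0)), n_tokens(sentence))
  for (fam in FEATURE_FAMILIES) {
    if (!fam %in% config$features) next
    fs <- switch(fam,
      token = token_features(sentence),
      orthographic = orthographic_features(sentence),
      morphological = morphological_features(
        sentence, config$ngram_sizes$morphological %||% c(2L, 3L)),
      sentence_length = sentence_length_features(sentence),
      concepts = concept_features(sentence),
      dictionary = dictionary_features(sentence, dictionaries),
      modifier = modifier_features(sentence),
      dependency_edge = dependency_edge_features(sentence),
      shortest_path = shortest_path_features(
        sentence,
        hop_limit = config$hops$shortest_path %||% 3L,
        vertex_feature = config$vertex$shortest_path %||% "lemma",
        ngram_sizes = config$ngram_sizes$shortest_path %||% c(2L, 3L)))
    out <- merge_token_lists(out, fs)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_context <- function(base, sentence, config) {
  ctx <- switch(config$context,
    none = NULL,
    window = apply_local_windows(sentence),
    conjunctions = apply_conjunctions(sentence),
    dependency_window = apply_dependency_windows(
      sentence, min(3L, config$hops$dependency_window %||% 3L)))
  if (is.null(ctx)) base else merge_token_lists(base, ctx)
}

#' Extract the feature instance of a sentence under a configuration
#'
#' Runs exactly the feature families active in `config` with its per-family
#' parameters, then the configured context mode. Output order is
#' deterministic (catalogue order, then context).
#'
#' @param sentence A `trig_sentence`.
#' @param config A `trig_config`.
#' @param dictionaries List of `trig_dictionary`/`trig_matcher` objects for
#'   the `dictionary` family.
#' @return List (one element per token) of character vectors of
#'   `"KEY=value"` feature strings.
#' @export
extract_features <- function(sentence, config, dictionaries = list()) {
  stopifnot(inherits(config, "trig_config"))
  lapply(apply_context(extract_base(sentence, config, dictionaries),
                       sentence, config),
         unname)
}

#' Union of model configurations
#'
#' Builds the superset configuration used for one-pass feature extraction
#' when annotating with several models: every family active in any
#' configuration is active, n-gram size sets are unioned, hop limits are
#' maximized, vertex feature types are unioned. Context modes are not
#' unioned; context is applied per model when filtering.
#'
#' @param configs List of `trig_config` objects.
#' @return A `trig_config` superset (context `"none"`).
#' @export
union_configs <- function(configs) {
  stopifnot(length(configs) >= 1L)
  feats <- unique(unlist(lapply(configs, function(c) c$features)))
  ngr <- list(); hop <- list(); vtx <- list()
  for (fam in NGRAM_FAMILIES) {
    v <- sort(unique(unlist(lapply(configs, function(c) c$ngram_sizes[[fam]]))))
    if (length(v)) ngr[[fam]] <- v
  }
  for (fam in c(HOP_FAMILIES, "dependency_window")) {
    v <- unlist(lapply(configs, function(c) c$hops[[fam]]))
    if (length(v)) hop[[fam]] <- max(v)
  }
  for (fam in VERTEX_FAMILIES) {
    v <- unique(unlist(lapply(configs, function(c) c$vertex[[fam]])))
    if (length(v)) vtx[[fam]] <- v
  }
  trig_config("UNION", features = feats, context = "none",
              ngram_sizes = ngr, hops = hop, vertex = vtx, order = 1L)
}

family_key_regex <- list(
  token = "^(W|LEMMA|POS|CHUNK)=",
  orthographic = "^(CAPS|COUNT_UPP|COUNT_DIGIT|LENGTH|SYMBOL)=",
  morphological = "^(PREFIX[0-9]+|SUFFIX[0-9]+|SHAPE)=",
  sentence_length = "^SENT_LEN=",
  concepts = "^(Concept=|CONCEPT_|NUM_)",
  dictionary = "^Trigger=",
  modifier = "^(SUBJ_OF_VERB|OBJ_OF_VERB|MOD_OF_NOUN|MODIFIER)=",
  dependency_edge = "^(IN_DEP_|OUT_DEP_)",
  shortest_path = "^(SPDistance=|SP_EDGE_PATH=|SP_EDGE_TYPE=)"
)

filter_token_strings <- function(strs, config) {
  keep <- rep(FALSE, length(strs))
  for (fam in config$features) {
    keep <- keep | grepl(family_key_regex[[fam]], strs)
    if (fam == "morphological") {
      for (k in config$ngram_sizes$morphological %||% integer(0))
        keep <- keep | startsWith(strs, paste0("CHARNG", k, "="))
    }
    if (fam == "shortest_path") {
      for (k in config$ngram_sizes$shortest_path %||% integer(0))
        keep <- keep | startsWith(strs, paste0("SP_EDGE_NG", k, "="))
      for (vt in config$vertex$shortest_path %||% character(0)) {
        keep <- keep | startsWith(strs, paste0("SP_VERTEX_PATH_", toupper(vt), "="))
        for (k in config$ngram_sizes$shortest_path %||% integer(0))
          keep <- keep | startsWith(strs,
                                    paste0("SP_VERTEX_NG", k, "_", toupper(vt), "="))
      }
    }
  }
  if ("shortest_path" %in% config$features) {
    spd <- strs[startsWith(strs, "SPDistance=")]
    if (length(spd)) {
      hops <- as.integer(sub("^SPDistance=", "", spd[1L]))
      if (hops > (config$hops$shortest_path %||% 3L))
        keep <- keep & !grepl("^SP", strs)   # drop all SP* for this token
    }
  }
  strs[keep]
}

#' Filter a superset feature instance down to one configuration
#'
#' Maps the instance extracted under [union_configs()] to exactly the
#' strings `config` would have produced directly, then applies the model's
#' own context mode. The equivalence
#' `filter_features(extract(union), config) == extract_features(config)`
#' is the correctness contract of one-pass multi-model annotation.
#'
#' @param instance Per-token feature list extracted under the union config.
#' @param sentence The sentence the instance was extracted from.
#' @param config The member `trig_config`.
#' @return Per-token feature list for `config`.
#' @export
filter_features <- function(instance, sentence, config) {
  base <- lapply(instance, filter_token_strings, config = config)
  lapply(apply_context(base, sentence, config), unname)
}
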