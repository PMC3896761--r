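# Corpus data model: sentences, tokens with a feature multimap, chunks,
# an undirected labeled dependency graph and a nesting-aware annotation tree.
# Token indices are 0-based throughout (matching the column format); character
# offsets are 0-based, end-exclusive, relative to the document text.

#' Create a text-bound annotation
#'
#' An annotation marks a span of document text as either a biomedical concept
#' (e.g. a `Protein` mention that events attach to) or an event trigger
#' (e.g. `Gene_expression`).
#'
#' @param id Identifier string (BioNLP style, e.g. `"T1"`), or `NA`.
#' @param type Concept or event type string.
#' @param start,end 0-based, end-exclusive character offsets into the document.
#' @param text The covered text; must equal the document slice.
#' @param kind `"concept"` or `"trigger"`.
#' @return An object of class `trig_annotation`.
#' @export
annotation <- function(id, type, start, end, text, kind = c("concept", "trigger")) {
  kind <- match.arg(kind)
  if (!is.numeric(start) || !is.numeric(end) || start >= end)
    stop("annotation requires start < end, got [", start, ",", end, ")")
  structure(
    list(id = as.character(id), type = as.character(type),
         start = as.integer(start), end = as.integer(end),
         text = as.character(text), kind = kind),
    class = "trig_annotation"
  )
}

#' @export
print.trig_annotation <- function(x, ...) {
  cat(sprintf("<%s> %s %s [%d,%d) \"%s\"\n",
              x$kind, if (is.na(x$id)) "-" else x$id, x$type, x$start, x$end, x$text))
  invisible(x)
}

## ---- annotation tree -------------------------------------------------------

ann_node <- function(ann) list(ann = ann, children = list(), ambiguous = FALSE)

#' Empty annotation tree
#'
#' The tree keeps concept and trigger spans nested by containment: a node's
#' span contains all of its descendants' spans, siblings are ordered by start
#' offset, and partially overlapping (intersecting) spans are kept as siblings
#' flagged ambiguous. The root is a virtual node spanning the whole sentence.
#'
#' @param start,end Character span of the sentence the tree belongs to.
#' @return An object of class `trig_anntree`.
#' @export
annotation_tree <- function(start = 0L, end = .Machine$integer.max) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 children = list()),
            class = "trig_anntree")
}

span_contains <- function(os, oe, is_, ie) os <= is_ && ie <= oe
span_intersects <- function(as_, ae, bs, be) as_ < be && bs < ae

# insert into a list of sibling nodes, returns the updated list
ann_insert_nodes <- function(nodes, ann) {
  # duplicate span+type+kind anywhere at this level -> unchanged
  for (nd in nodes) {
    a <- nd$ann
    if (a$start == ann$start && a$end == ann$end &&
        a$type == ann$type && a$kind == ann$kind)
      return(nodes)
  }
  # fully contained in an existing sibling -> descend
  for (i in seq_along(nodes)) {
    a <- nodes[[i]]$ann
    if (span_contains(a$start, a$end, ann$start, ann$end) &&
        !(a$start == ann$start && a$end == ann$end)) {
      nodes[[i]]$children <- ann_insert_nodes(nodes[[i]]$children, ann)
      return(nodes)
    }
  }
  new <- ann_node(ann)
  keep <- list()
  for (nd in nodes) {
    a <- nd$ann
    if (span_contains(ann$start, ann$end, a$start, a$end)) {
      new$children <- c(new$children, list(nd))        # re-parent
    } else {
      if (span_intersects(ann$start, ann$end, a$start, a$end)) {
        nd$ambiguous <- TRUE
        new$ambiguous <- TRUE
      }
      keep <- c(keep, list(nd))
    }
  }
  keep <- c(keep, list(new))
  ord <- order(vapply(keep, function(n) n$ann$start, integer(1)),
               vapply(keep, function(n) n$ann$end, integer(1)))
  keep[ord]
}

#' Insert an annotation into a tree
#'
#' Containment nesting is restored automatically (an inserted span adopts the
#' existing spans it contains); exact duplicates (same span, type and kind)
#' are collapsed.
#'
#' @param tree A `trig_anntree`.
#' @param ann A `trig_annotation` whose span lies inside the tree's span.
#' @return The updated tree.
#' @export
insert_annotation <- function(tree, ann) {
  stopifnot(inherits(tree, "trig_anntree"), inherits(ann, "trig_annotation"))
  if (ann$start < tree$start || ann$end > tree$end)
    stop("annotation span [", ann$start, ",", ann$end,
         ") outside sentence span [", tree$start, ",", tree$end, ")")
  tree$children <- ann_insert_nodes(tree$children, ann)
  tree
}

flatten_nodes <- function(nodes) {
  out <- list()
  for (nd in nodes) {
    out <- c(out, list(nd$ann), flatten_nodes(nd$children))
  }
  out
}

#' List the annotations held by a tree
#'
#' @param tree A `trig_anntree`.
#' @param kind Optional filter: `"concept"` or `"trigger"`.
#' @param type Optional filter on the annotation type string.
#' @return List of `trig_annotation` objects in pre-order.
#' @export
tree_annotations <- function(tree, kind = NULL, type = NULL) {
  anns <- flatten_nodes(tree$children)
  if (!is.null(kind)) anns <- Filter(function(a) a$kind == kind, anns)
  if (!is.null(type)) anns <- Filter(function(a) a$type %in% type, anns)
  anns
}

# parent/child span pairs, for invariant checks
tree_edges <- function(tree) {
  rec <- function(nodes) {
    out <- list()
    for (nd in nodes) {
      for (ch in nd$children)
        out <- c(out, list(list(parent = nd$ann, child = ch$ann)))
      out <- c(out, rec(nd$children))
    }
    out
  }
  rec(tree$children)
}

## ---- sentence construction -------------------------------------------------

#' Assemble a sentence from parsed token records
#'
#' Builds the in-memory sentence structure from reader output: tokens with
#' offsets, lemma and POS stored in the per-token feature multimap, chunk
#' records collapsed from BIO tags, and an undirected labeled dependency
#' graph built from head/label columns (head--dependent direction is kept as
#' edge metadata for the modifier and in/out-dependency features).
#'
#' @param token_rows Data frame with columns `text`, `start`, `end` and
#'   optionally `lemma`, `pos`. Offsets are 0-based, end-exclusive, document
#'   relative, strictly increasing.
#' @param dep_edges Data frame with columns `head`, `dep` (0-based token
#'   indices) and `label`, or `NULL` for an edgeless sentence. Alternatively
#'   supply per-token `head` (1-based, 0 = root) via `head_col`/`label_col`
#'   in `token_rows` through [read_parsed_corpus()].
#' @param chunk_tags Character vector of per-token BIO chunk tags
#'   (`"B-NP"`, `"I-NP"`, `"O"`, ...), or `NULL`.
#' @param doc_text Full document text (used to validate offsets when given).
#' @return An object of class `trig_sentence`.
#' @export
build_sentence <- function(token_rows, dep_edges = NULL, chunk_tags = NULL,
                           doc_text = NULL) {
  n <- nrow(token_rows)
  if (n == 0L) stop("cannot build a sentence from zero tokens")
  start <- as.integer(token_rows$start)
  end <- as.integer(token_rows$end)
  for (i in seq_len(n)) {
    if (start[i] >= end[i])
      stop("malformed token ", i - 1L, ": start >= end")
    if (i > 1L && start[i] < end[i - 1L])
      stop("malformed token ", i - 1L, ": offset overlaps previous token")
    if (!is.null(doc_text)) {
      slice <- substr(doc_text, start[i] + 1L, end[i])
      if (slice != token_rows$text[i])
        stop("malformed token ", i - 1L, ": text \"", token_rows$text[i],
             "\" does not match document slice \"", slice, "\"")
    }
  }
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    mm <- list()
    if (!is.null(token_rows$lemma) && !is.na(token_rows$lemma[i]))
      mm$LEMMA <- token_rows$lemma[i]
    if (!is.null(token_rows$pos) && !is.na(token_rows$pos[i]))
      mm$POS <- token_rows$pos[i]
    feats[[i]] <- mm
  }

  edges <- data.frame(head = integer(0), dep = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (!is.null(dep_edges) && nrow(dep_edges) > 0L) {
    h <- as.integer(dep_edges$head); d <- as.integer(dep_edges$dep)
    bad <- which(h < 0L | h >= n | d < 0L | d >= n)
    if (length(bad))
      stop("malformed token ", d[bad[1L]],
           ": head index ", h[bad[1L]], " out of range")
    if (any(h == d))
      stop("malformed token ", d[which(h == d)[1L]], ": self-loop dependency")
    key <- paste(pmin(h, d), pmax(h, d))
    keep <- !duplicated(key)
    edges <- data.frame(head = h[keep], dep = d[keep],
                        label = as.character(dep_edges$label)[keep],
                        stringsAsFactors = FALSE)
  }

  chunks <- data.frame(label = character(0), first = integer(0),
                       last = integer(0), stringsAsFactors = FALSE)
  if (!is.null(chunk_tags)) {
    stopifnot(length(chunk_tags) == n)
    lab <- NULL; first <- NA_integer_
    rows <- list()
    flush <- function(i) {
      if (!is.null(lab))
        rows[[length(rows) + 1L]] <<- data.frame(
          label = lab, first = first, last = i - 1L, stringsAsFactors = FALSE)
      lab <<- NULL
    }
    for (i in seq_len(n)) {
      tg <- chunk_tags[i]
      if (is.na(tg) || tg == "O") { flush(i - 1L) }
      else if (startsWith(tg, "B-")) { flush(i - 1L); lab <- substring(tg, 3L); first <- i - 1L }
      else if (startsWith(tg, "I-")) {
        cont <- substring(tg, 3L)
        if (is.null(lab) || lab != cont) { flush(i - 1L); lab <- cont; first <- i - 1L }
      } else stop("unrecognized chunk tag \"", tg, "\" at token ", i - 1L)
    }
    flush(n)
    if (length(rows)) chunks <- do.call(rbind, rows)
  }

  sent_text <- if (!is.null(doc_text))
    substr(doc_text, start[1L] + 1L, end[n]) else NA_character_
  structure(
    list(tokens = data.frame(text = as.character(token_rows$text),
                             start = start, end = end,
                             stringsAsFactors = FALSE),
         feats = feats, chunks = chunks, edges = edges,
         annotations = annotation_tree(start[1L], end[n]),
         start = start[1L], end = end[n], text = sent_text),
    class = "trig_sentence"
  )
}

#' @export
print.trig_sentence <- function(x, ...) {
  cat(sprintf("<trig_sentence> %d tokens, %d edges, %d chunks, %d annotations [%d,%d)\n",
              n_tokens(x), nrow(x$edges), nrow(x$chunks),
              length(tree_annotations(x$annotations)), x$start, x$end))
  invisible(x)
}

n_tokens <- function(sentence) nrow(sentence$tokens)

# feature multimap accessors: first value (or fallback) / append
tok_feat1 <- function(sentence, i, key, default = NA_character_) {
  v <- sentence$feats[[i + 1L]][[key]]
  if (is.null(v) || !length(v)) default else v[[1L]]
}
tok_lemma <- function(sentence, i) {
  v <- tok_feat1(sentence, i, "LEMMA")
  if (is.na(v)) sentence$tokens$text[i + 1L] else v
}
tok_pos <- function(sentence, i) tok_feat1(sentence, i, "POS")

# per-token BIO chunk tags and bare chunk label ("O" when unchunked)
chunk_bio_tags <- function(sentence) {
  n <- n_tokens(sentence)
  out <- rep("O", n)
  ch <- sentence$chunks
  if (nrow(ch)) for (r in seq_len(nrow(ch))) {
    rng <- (ch$first[r]:ch$last[r]) + 1L
    out[rng] <- paste0("I-", ch$label[r])
    out[rng[1L]] <- paste0("B-", ch$label[r])
  }
  out
}
chunk_label_of <- function(sentence, i) {
  ch <- sentence$chunks
  if (nrow(ch)) for (r in seq_len(nrow(ch)))
    if (i >= ch$first[r] && i <= ch$last[r]) return(ch$label[r])
  "O"
}

## ---- dependency graph queries ----------------------------------------------

adjacency <- function(sentence) {
  n <- n_tokens(sentence)
  adj <- vector("list", n)
  e <- sentence$edges
  if (nrow(e)) for (r in seq_len(nrow(e))) {
    a <- e$head[r] + 1L; b <- e$dep[r] + 1L
    adj[[a]] <- c(adj[[a]], b - 1L)
    adj[[b]] <- c(adj[[b]], a - 1L)
  }
  lapply(adj, function(v) sort(unique(v)))
}

edge_label_between <- function(sentence, a, b) {
  e <- sentence$edges
  hit <- which((e$head == a & e$dep == b) | (e$head == b & e$dep == a))
  if (!length(hit)) NA_character_ else e$label[hit[1L]]
}

bfs_dist <- function(adj, from) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[from + 1L] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) for (v in adj[[u + 1L]])
      if (is.na(dist[v + 1L])) { dist[v + 1L] <- dist[u + 1L] + 1L; nxt <- c(nxt, v) }
    frontier <- nxt
  }
  dist
}

token_path <- function(vertices, labels) {
  structure(list(vertices = as.integer(vertices),
                 labels = as.character(labels),
                 hops = length(vertices) - 1L),
            class = "trig_path")
}

#' @export
print.trig_path <- function(x, ...) {
  cat(sprintf("<trig_path> %d hops: %s\n", x$hops,
              paste(x$vertices, collapse = " - ")))
  invisible(x)
}

#' Minimum-hop path between two tokens of a sentence
#'
#' Unit-weight shortest path over the undirected dependency graph. Among
#' equal-length paths the lexicographically smallest vertex-index sequence is
#' returned, so extracted path features are reproducible.
#'
#' @param sentence A `trig_sentence`.
#' @param from,to 0-based token indices.
#' @return A `trig_path` (vertex sequence, edge labels, hop count), or `NULL`
#'   if the tokens are disconnected.
#' @export
shortest_path <- function(sentence, from, to) {
  n <- n_tokens(sentence)
  stopifnot(from >= 0L, from < n, to >= 0L, to < n)
  if (from == to) return(token_path(from, character(0)))
  adj <- adjacency(sentence)
  dist_to <- bfs_dist(adj, to)
  if (is.na(dist_to[from + 1L])) return(NULL)
  path <- from
  cur <- from
  while (cur != to) {
    nbr <- adj[[cur + 1L]]
    down <- nbr[!is.na(dist_to[nbr + 1L]) & dist_to[nbr + 1L] == dist_to[cur + 1L] - 1L]
    cur <- min(down)   # smallest index => lexicographically smallest sequence
    path <- c(path, cur)
  }
  labels <- vapply(seq_len(length(path) - 1L), function(k)
    edge_label_between(sentence, path[k], path[k + 1L]), character(1))
  token_path(path, labels)
}

# 0-based indices of tokens covered by any concept annotation
concept_token_set <- function(sentence) {
  anns <- tree_annotations(sentence$annotations, kind = "concept")
  if (!length(anns)) return(integer(0))
  tk <- sentence$tokens
  idx <- integer(0)
  for (a in anns) {
    covered <- which(tk$start >= a$start & tk$end <= a$end) - 1L
    idx <- c(idx, covered)
  }
  sort(unique(idx))
}

#' Shortest path from a token to the closest concept mention
#'
#' Among all tokens belonging to any concept annotation of the sentence,
#' finds the one with the minimum-hop dependency path from `from` (ties
#' broken toward the smallest target token index). A token inside a concept
#' yields a 0-hop path.
#'
#' @param sentence A `trig_sentence` carrying concept annotations.
#' @param from 0-based token index.
#' @return A `trig_path`, or `NULL` when the sentence has no concepts or the
#'   token is disconnected from all of them.
#' @export
closest_concept_path <- function(sentence, from) {
  targets <- concept_token_set(sentence)
  if (!length(targets)) return(NULL)
  if (from %in% targets) return(token_path(from, character(0)))
  adj <- adjacency(sentence)
  dist <- bfs_dist(adj, from)
  d <- dist[targets + 1L]
  ok <- which(!is.na(d))
  if (!length(ok)) return(NULL)
  best <- ok[order(d[ok], targets[ok])][1L]
  shortest_path(sentence, from, targets[best])
}

## ---- documents and corpora -------------------------------------------------

#' Construct a document
#'
#' @param id Document identifier.
#' @param text Full document text.
#' @param sentences List of `trig_sentence` objects with disjoint, ordered
#'   spans inside `text`.
#' @return An object of class `trig_document`.
#' @export
document <- function(id, text, sentences) {
  if (length(sentences) > 1L) {
    st <- vapply(sentences, function(s) s$start, integer(1))
    en <- vapply(sentences, function(s) s$end, integer(1))
    if (any(st[-1L] < en[-length(en)]))
      stop("sentence spans of document ", id, " overlap or are unordered")
  }
  structure(list(id = as.character(id), text = text, sentences = sentences),
            class = "trig_document")
}

#' @export
print.trig_document <- function(x, ...) {
  cat(sprintf("<trig_document> %s: %d sentences, %d chars\n",
              x$id, length(x$sentences), nchar(x$text)))
  invisible(x)
}

#' Bundle documents into a corpus
#' @param documents List of `trig_document` objects.
#' @return An object of class `trig_corpus`.
#' @export
corpus <- function(documents) {
  structure(documents, class = "trig_corpus")
}

#' @export
print.trig_corpus <- function(x, ...) {
  cat(sprintf("<trig_corpus> %d documents, %d sentences\n", length(x),
              sum(vapply(x, function(d) length(d$sentences), integer(1)))))
  invisible(x)
}

#' Attach annotations to the sentences of a document
#'
#' Each annotation is inserted into the tree of the sentence containing its
#' span; a span crossing sentence boundaries is a range error.
#'
#' @param doc A `trig_document`.
#' @param anns List of `trig_annotation` objects.
#' @return The updated document.
#' @export
attach_annotations <- function(doc, anns) {
  for (a in anns) {
    placed <- FALSE
    for (i in seq_along(doc$sentences)) {
      s <- doc$sentences[[i]]
      if (a$start >= s$start && a$end <= s$end) {
        doc$sentences[[i]]$annotations <- insert_annotation(s$annotations, a)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("annotation ", a$id, " [", a$start, ",", a$end,
           ") does not fit inside any sentence of document ", doc$id)
  }
  doc
}

#' Collect the annotations of a document
#' @param doc A `trig_document`.
#' @inheritParams tree_annotations
#' @return List of `trig_annotation` objects ordered by start offset.
#' @export
doc_annotations <- function(doc, kind = NULL, type = NULL) {
  anns <- list()
  for (s in doc$sentences)
    anns <- c(anns, tree_annotations(s$annotations, kind = kind, type = type))
  if (length(anns))
    anns <- anns[order(vapply(anns, function(a) a$start, integer(1)),
                       vapply(anns, function(a) a$end, integer(1)))]
  anns
}

# drop annotations (by identity of span+type+kind) from a document's trees
remove_annotations <- function(doc, drop) {
  if (!length(drop)) return(doc)
  keys <- vapply(drop, function(a) paste(a$kind, a$type, a$start, a$end), character(1))
  for (i in seq_along(doc$sentences)) {
    s <- doc$sentences[[i]]
    keep <- Filter(function(a)
      !(paste(a$kind, a$type, a$start, a$end) %in% keys),
      tree_annotations(s$annotations))
    tree <- annotation_tree(s$start, s$end)
    for (a in keep) tree <- insert_annotation(tree, a)
    doc$sentences[[i]]$annotations <- tree
  }
  doc
}
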