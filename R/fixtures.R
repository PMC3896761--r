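# Deterministic toy corpora for end-to-end testing, plus the frozen
# worked-example sentence used throughout the documentation: IRF4
# down-regulation in leukemic cells, with one Protein concept and two event
# triggers. The example's dependency parse is only partly determined by the
# feature strings it must reproduce (the in/out edges of "regulation", its
# 1-hop neighborhood, and the 3-hop path to the closest concept token); the
# remaining edges are chosen once and frozen here.

#' The bundled worked-example document
#'
#' One sentence, "Down-regulation of interferon regulatory factor 4 gene
#' expression in leukemic cells.", fully parsed: 14 tokens with offsets,
#' lemmas, POS tags and chunk tags, an undirected labeled dependency graph,
#' one `Protein` concept annotation over "interferon regulatory factor 4",
#' and gold triggers `Negative_regulation` ("Down-regulation") and
#' `Gene_expression` ("expression"). The hyphen token carries the lemma
#' − (minus sign) as produced by the upstream parser.
#'
#' @return A `trig_document` with id `"irf4"`.
#' @export
irf4_example <- function() {
  text <- "Down-regulation of interferon regulatory factor 4 gene expression in leukemic cells."
  rows <- data.frame(
    text = c("Down", "-", "regulation", "of", "interferon", "regulatory",
             "factor", "4", "gene", "expression", "in", "leukemic",
             "cells", "."),
    start = c(0L, 4L, 5L, 16L, 19L, 30L, 41L, 48L, 50L, 55L, 66L, 69L, 78L, 83L),
    end = c(4L, 5L, 15L, 18L, 29L, 40L, 47L, 49L, 54L, 65L, 68L, 77L, 83L, 84L),
    lemma = c("down", "−", "regulation", "of", "interferon", "regulatory",
              "factor", "4", "gene", "expression", "in", "leukemic",
              "cell", "."),
    pos = c("NN", "HYPH", "NN", "PP", "NN", "JJ", "NN", "CD", "NN", "NN",
            "PP", "JJ", "NNS", "."),
    stringsAsFactors = FALSE)
  chunk <- c("B-NP", "O", "B-NP", "B-PP", "B-NP", "I-NP", "I-NP", "I-NP",
             "I-NP", "I-NP", "B-PP", "B-NP", "I-NP", "O")
  edges <- data.frame(
    head = c(1L, 2L, 10L, 2L, 3L, 9L, 9L, 8L, 6L, 6L, 10L, 12L, 12L),
    dep =  c(0L, 1L, 2L,  3L, 9L, 7L, 8L, 6L, 4L, 5L, 12L, 11L, 13L),
    label = c("NMOD", "OBJ", "NMOD", "NMOD", "PMOD", "NMOD", "NMOD",
              "NMOD", "NMOD", "NMOD", "PMOD", "NMOD", "P"),
    stringsAsFactors = FALSE)
  s <- build_sentence(rows, dep_edges = edges, chunk_tags = chunk,
                      doc_text = text)
  doc <- document("irf4", text, list(s))
  attach_annotations(doc, list(
    annotation("T1", "Protein", 19L, 49L, "interferon regulatory factor 4",
               kind = "concept"),
    annotation("T2", "Negative_regulation", 0L, 15L, "Down-regulation",
               kind = "trigger"),
    annotation("T3", "Gene_expression", 55L, 65L, "expression",
               kind = "trigger")))
}

## ---- synthetic corpus generator --------------------------------------------

DEFAULT_CONCEPTS <- c("IRF4", "TP53", "STAT3", "IL2", "TNF", "BRCA1",
                      "MYC", "EGFR", "FOXP3", "GATA1")
DEFAULT_LEXICONS <- list(
  Gene_expression = c("expression", "coexpression", "production",
                      "synthesis", "transcription"),
  Positive_regulation = c("activation", "induction", "upregulation",
                          "stimulation", "enhancement"))
CELL_WORDS <- c("leukemic", "HeLa", "Jurkat", "myeloid")
GEN_DEP_LABELS <- c("SUB", "OBJ", "NMOD", "PMOD", "VMOD")

# sentence templates as token vectors; slots: <TRIG>, <CONC>, <CELL>
TRIGGER_PATTERNS <- list(
  c("we", "observed", "<TRIG>", "of", "<CONC>", "in", "<CELL>", "cells", "."),
  c("<CONC>", "<TRIG>", "was", "reduced", "in", "<CELL>", "cells", "."))
NOISE_PATTERNS <- list(
  c("the", "<TRIG>", "profile", "of", "<CONC>", "was", "normal", "."),
  c("the", "<TRIG>", "level", "in", "<CONC>", "samples", "was", "unchanged", "."))
PLAIN_PATTERNS <- list(
  c("<CONC>", "binds", "<CONC>", "in", "<CELL>", "cells", "."),
  c("the", "role", "of", "<CONC>", "remains", "unclear", "."))

GEN_POS <- c(we = "PRP", observed = "VBD", of = "PP", "in" = "PP", was = "VBD",
             reduced = "VBN", cells = "NNS", "." = ".", the = "DT",
             profile = "NN", level = "NN", samples = "NNS", normal = "JJ",
             unchanged = "JJ", binds = "VBZ", role = "NN", remains = "VBZ",
             unclear = "JJ")

#' Describe a synthetic trigger corpus
#'
#' The generator emulates the layout a trigger recognizer faces: protein
#' mentions (annotated concepts), per-type trigger lexicons whose words are
#' gold triggers when they occur in trigger contexts, the same words as
#' distractors in noise contexts (controlled by `noise_rate`), function-word
#' filler, random projective dependency parses, and sentences without any
#' trigger word (`plain_rate`).
#'
#' @param n_documents Number of documents.
#' @param sentences_per_doc Sentences per document.
#' @param trigger_lexicons Named list: event type -> character vector of
#'   trigger words (disjoint from the function-word vocabulary).
#' @param concept_lexicon Protein-like names used for concept mentions.
#' @param noise_rate Fraction of trigger-lexicon emissions placed in
#'   non-trigger contexts, in `[0,1]`.
#' @param plain_rate Fraction of sentences with no trigger-lexicon word.
#' @param seed Integer seed; generation is byte-identical under a fixed seed.
#' @return An object of class `trig_fixture_spec`.
#' @export
fixture_spec <- function(n_documents = 20L, sentences_per_doc = 8L,
                         trigger_lexicons = DEFAULT_LEXICONS,
                         concept_lexicon = DEFAULT_CONCEPTS,
                         noise_rate = 0.2, plain_rate = 0.2, seed = 42L) {
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0,1]")
  if (!length(trigger_lexicons) || any(!lengths(trigger_lexicons)))
    stop("every requested event type needs a non-empty lexicon")
  reserved <- unique(c(names(GEN_POS), CELL_WORDS))
  clash <- intersect(tolower(unlist(trigger_lexicons)), reserved)
  if (length(clash))
    stop("trigger lexicon overlaps the function-word vocabulary: ",
         paste(clash, collapse = ", "))
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 trigger_lexicons = trigger_lexicons,
                 concept_lexicon = concept_lexicon,
                 noise_rate = noise_rate, plain_rate = plain_rate,
                 seed = as.integer(seed)),
            class = "trig_fixture_spec")
}

gen_pos_of <- function(w) {
  if (w %in% names(GEN_POS)) GEN_POS[[w]] else "NN"
}

# random projective dependency tree over 0-based indices [lo, hi]
gen_projective <- function(lo, hi, edges_env) {
  root <- if (lo == hi) lo else sample(lo:hi, 1L)
  if (root > lo) {
    lr <- gen_projective(lo, root - 1L, edges_env)
    edges_env$rows[[length(edges_env$rows) + 1L]] <-
      c(root, lr, sample(length(GEN_DEP_LABELS), 1L))
  }
  if (root < hi) {
    rr <- gen_projective(root + 1L, hi, edges_env)
    edges_env$rows[[length(edges_env$rows) + 1L]] <-
      c(root, rr, sample(length(GEN_DEP_LABELS), 1L))
  }
  root
}

gen_sentence_tokens <- function(spec) {
  types <- names(spec$trigger_lexicons)
  u <- runif(1L)
  kind <- if (u < spec$plain_rate) "plain"
          else if (u < spec$plain_rate + (1 - spec$plain_rate) * spec$noise_rate) "noise"
          else "trigger"
  pat <- switch(kind,
    plain = PLAIN_PATTERNS[[sample(length(PLAIN_PATTERNS), 1L)]],
    noise = NOISE_PATTERNS[[sample(length(NOISE_PATTERNS), 1L)]],
    trigger = TRIGGER_PATTERNS[[sample(length(TRIGGER_PATTERNS), 1L)]])
  type <- types[sample(length(types), 1L)]
  words <- character(length(pat))
  concept_slots <- integer(0); trig_slot <- NA_integer_
  for (i in seq_along(pat)) {
    w <- pat[i]
    if (w == "<TRIG>") {
      lex <- spec$trigger_lexicons[[type]]
      words[i] <- lex[sample(length(lex), 1L)]
      trig_slot <- i
    } else if (w == "<CONC>") {
      words[i] <- spec$concept_lexicon[sample(length(spec$concept_lexicon), 1L)]
      concept_slots <- c(concept_slots, i)
    } else if (w == "<CELL>") {
      words[i] <- CELL_WORDS[sample(length(CELL_WORDS), 1L)]
    } else words[i] <- w
  }
  list(words = words, concept_slots = concept_slots,
       trig_slot = if (kind == "trigger") trig_slot else NA_integer_,
       type = type)
}

gen_document <- function(spec, doc_id) {
  sent_specs <- lapply(seq_len(spec$sentences_per_doc),
                       function(i) gen_sentence_tokens(spec))
  # assemble text: tokens single-spaced, sentences newline-separated
  sentences <- list(); anns <- list(); offset <- 0L; text_parts <- character(0)
  tcount <- 0L
  for (ss in sent_specs) {
    words <- ss$words
    n <- length(words)
    starts <- integer(n); ends <- integer(n); pos <- offset
    for (i in seq_len(n)) {
      starts[i] <- pos; ends[i] <- pos + nchar(words[i])
      pos <- ends[i] + 1L
    }
    sent_text <- paste(words, collapse = " ")
    text_parts <- c(text_parts, sent_text)
    postags <- vapply(words, gen_pos_of, character(1))
    chunk <- character(n); open <- FALSE
    for (i in seq_len(n)) {
      p <- postags[i]
      if (p %in% c("NN", "NNS", "CD", "DT", "JJ", "PRP")) {
        chunk[i] <- if (open) "I-NP" else "B-NP"; open <- TRUE
      } else if (startsWith(p, "V")) { chunk[i] <- "B-VP"; open <- FALSE }
      else if (p == "PP") { chunk[i] <- "B-PP"; open <- FALSE }
      else { chunk[i] <- "O"; open <- FALSE }
    }
    env <- new.env(); env$rows <- list()
    gen_projective(0L, n - 1L, env)
    edges <- if (length(env$rows)) {
      m <- do.call(rbind, env$rows)
      data.frame(head = m[, 1L], dep = m[, 2L],
                 label = GEN_DEP_LABELS[m[, 3L]], stringsAsFactors = FALSE)
    } else NULL
    rows <- data.frame(text = words, start = starts, end = ends,
                       lemma = tolower(words), pos = postags,
                       stringsAsFactors = FALSE)
    sentences[[length(sentences) + 1L]] <-
      list(rows = rows, edges = edges, chunk = chunk, ss = ss)
    offset <- pos
  }
  text <- paste(text_parts, collapse = "\n")
  built <- lapply(sentences, function(sn)
    build_sentence(sn$rows, dep_edges = sn$edges, chunk_tags = sn$chunk,
                   doc_text = text))
  doc <- document(doc_id, text, built)
  next_id <- 1L
  for (k in seq_along(sentences)) {
    sn <- sentences[[k]]
    for (ci in sn$ss$concept_slots) {
      a <- annotation(paste0("T", next_id), "Protein",
                      sn$rows$start[ci], sn$rows$end[ci],
                      sn$rows$text[ci], kind = "concept")
      next_id <- next_id + 1L
      doc <- attach_annotations(doc, list(a))
    }
    if (!is.na(sn$ss$trig_slot)) {
      ti <- sn$ss$trig_slot
      a <- annotation(paste0("T", next_id), sn$ss$type,
                      sn$rows$start[ti], sn$rows$end[ti],
                      sn$rows$text[ti], kind = "trigger")
      next_id <- next_id + 1L
      doc <- attach_annotations(doc, list(a))
    }
  }
  doc
}

#' Generate a synthetic trigger corpus
#'
#' @param spec A `trig_fixture_spec`.
#' @return A `trig_corpus` with gold concept and trigger annotations.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "trig_fixture_spec"))
  with_seed(spec$seed, {
    corpus(lapply(seq_len(spec$n_documents), function(d)
      gen_document(spec, sprintf("doc%03d", d))))
  })
}

#' Write a corpus to canonical on-disk form
#'
#' Per document: `<id>.txt` (raw text), `<id>.conll` (token table),
#' `<id>.a1` (concept annotations) and, when gold triggers are present,
#' `<id>.a1t` (trigger annotations, same A1 layout).
#'
#' @param corp A `trig_corpus`.
#' @param dir Output directory (created if missing).
#' @export
write_corpus_files <- function(corp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corp) {
    base <- file.path(dir, doc$id)
    write_parsed_corpus(doc, paste0(base, ".txt"), paste0(base, ".conll"))
    write_a1(doc_annotations(doc, kind = "concept"), paste0(base, ".a1"))
    trig <- doc_annotations(doc, kind = "trigger")
    if (length(trig)) write_a1(trig, paste0(base, ".a1t"))
  }
  invisible(corp)
}

#' Read a corpus directory written by [write_corpus_files()]
#'
#' @param dir Directory with `<id>.txt` / `<id>.conll` (and optionally
#'   `<id>.a1`, `<id>.a1t`) files.
#' @param triggers Load gold triggers from `.a1t` files when present.
#' @return A `trig_corpus`.
#' @export
read_corpus_dir <- function(dir, triggers = TRUE) {
  txts <- sort(Sys.glob(file.path(dir, "*.txt")))
  if (!length(txts)) stop("no .txt documents found in ", dir)
  docs <- lapply(txts, function(tf) {
    base <- sub("\\.txt$", "", tf)
    doc <- read_parsed_corpus(tf, paste0(base, ".conll"))
    if (file.exists(paste0(base, ".a1")))
      doc <- attach_annotations(doc, read_a1(paste0(base, ".a1"), doc,
                                             kind = "concept"))
    if (triggers && file.exists(paste0(base, ".a1t")))
      doc <- attach_annotations(doc, read_a1(paste0(base, ".a1t"), doc,
                                             kind = "trigger"))
    doc
  })
  corpus(docs)
}
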