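# Readers and writers: raw text + CoNLL-style token tables, BioNLP A1
# standoff, TSV trigger dictionaries, and A1/JSON/XML trigger output.
#
# The canonical pre-processed token table is one token per line, blank line
# between sentences, 9 tab-separated columns:
#   index  text  start  end  lemma  pos  chunk-BIO  head  deplabel
# with 0-based token index, 0-based end-exclusive document offsets, and a
# 1-based head column where 0 marks the root. This is classic CoNLL-X plus
# character offsets and a chunk column, which the feature set needs.

CONLL_COLS <- c("index", "text", "start", "end", "lemma", "pos",
                "chunk", "head", "deplabel")

#' Read a pre-parsed document
#'
#' Consumes the output of the external NLP pre-processing stage (sentence
#' splitting, tokenization, lemmatization, POS tagging, chunking and
#' dependency parsing) as a raw-text file plus a CoNLL-style token table,
#' and assembles the in-memory document structure.
#'
#' @param text_file Path to the plain-text document (UTF-8).
#' @param conll_file Path to the 9-column token table (see package docs).
#' @param id Document identifier; defaults to the text file's base name.
#' @return A `trig_document`.
#' @export
read_parsed_corpus <- function(text_file, conll_file, id = NULL) {
  text <- paste(readLines(text_file, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(text_file))
  lines <- readLines(conll_file, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  block <- list(); block_lines <- integer(0)
  flush_block <- function() {
    if (!length(block)) return()
    rows <- do.call(rbind, block)
    sentences[[length(sentences) + 1L]] <<- conll_block_to_sentence(rows, text, block_lines[1L])
    block <<- list(); block_lines <<- integer(0)
  }
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    if (!nzchar(trimws(raw))) { flush_block(); next }
    f <- strsplit(raw, "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(CONLL_COLS))
      stop("parse error at line ", ln, ": expected ", length(CONLL_COLS),
           " tab-separated columns, found ", length(f))
    block[[length(block) + 1L]] <- data.frame(
      index = as.integer(f[1L]), text = f[2L],
      start = as.integer(f[3L]), end = as.integer(f[4L]),
      lemma = f[5L], pos = f[6L], chunk = f[7L],
      head = as.integer(f[8L]), deplabel = f[9L],
      stringsAsFactors = FALSE)
    block_lines <- c(block_lines, ln)
  }
  flush_block()
  document(id, text, sentences)
}

conll_block_to_sentence <- function(rows, text, first_line) {
  n <- nrow(rows)
  for (i in seq_len(n)) {
    slice <- substr(text, rows$start[i] + 1L, rows$end[i])
    if (slice != rows$text[i])
      stop("alignment error near line ", first_line + i - 1L, ": token \"",
           rows$text[i], "\" not found at offsets [", rows$start[i], ",",
           rows$end[i], ")")
  }
  has_head <- rows$head > 0L
  dep_edges <- if (any(has_head)) data.frame(
    head = rows$head[has_head] - 1L,
    dep = rows$index[has_head],
    label = rows$deplabel[has_head],
    stringsAsFactors = FALSE) else NULL
  build_sentence(rows[, c("text", "start", "end", "lemma", "pos")],
                 dep_edges = dep_edges, chunk_tags = rows$chunk,
                 doc_text = text)
}

#' Write a document back to text + CoNLL-style files
#'
#' Inverse of [read_parsed_corpus()] on valid data (round-trip safe).
#'
#' @param doc A `trig_document`.
#' @param text_file,conll_file Output paths.
#' @export
write_parsed_corpus <- function(doc, text_file, conll_file) {
  writeLines(doc$text, text_file, useBytes = TRUE)
  con <- file(conll_file, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in doc$sentences) {
    n <- n_tokens(s)
    heads <- rep(0L, n); labels <- rep("ROOT", n)
    if (nrow(s$edges)) for (r in seq_len(nrow(s$edges))) {
      heads[s$edges$dep[r] + 1L] <- s$edges$head[r] + 1L
      labels[s$edges$dep[r] + 1L] <- s$edges$label[r]
    }
    bio <- chunk_bio_tags(s)
    for (i in seq_len(n)) {
      writeLines(paste(i - 1L, s$tokens$text[i], s$tokens$start[i],
                       s$tokens$end[i], tok_lemma(s, i - 1L),
                       tok_pos(s, i - 1L), bio[i], heads[i], labels[i],
                       sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(doc)
}

## ---- A1 standoff -----------------------------------------------------------

#' Read BioNLP A1 standoff annotations
#'
#' Lines have the form `T<id><TAB><type> <start> <end><TAB><text>`. Lines not
#' starting with `T` are ignored with a warning. When a document is supplied
#' the covered text is checked against the document slice.
#'
#' @param file Path to the `.a1` file.
#' @param doc Optional `trig_document` for integrity checking.
#' @param kind Stored annotation kind, `"concept"` (default) or `"trigger"`.
#' @return List of `trig_annotation` objects.
#' @export
read_a1 <- function(file, doc = NULL, kind = "concept") {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  anns <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    if (!nzchar(trimws(raw))) next
    if (!startsWith(raw, "T")) {
      warning("ignoring non text-bound line ", ln, ": ", raw)
      next
    }
    f <- strsplit(raw, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("parse error at line ", ln, ": expected 3 tab-separated fields")
    mid <- strsplit(f[2L], " ", fixed = TRUE)[[1L]]
    if (length(mid) != 3L)
      stop("parse error at line ", ln, ": expected \"type start end\"")
    a <- annotation(f[1L], mid[1L], as.integer(mid[2L]), as.integer(mid[3L]),
                    f[3L], kind = kind)
    if (!is.null(doc)) {
      slice <- substr(doc$text, a$start + 1L, a$end)
      if (slice != a$text)
        stop("integrity error for annotation ", a$id, ": text \"", a$text,
             "\" does not match document slice \"", slice, "\"")
    }
    anns[[length(anns) + 1L]] <- a
  }
  anns
}

a1_line <- function(a) {
  paste0(a$id, "\t", a$type, " ", a$start, " ", a$end, "\t", a$text)
}

#' Write annotations in A1 standoff format
#'
#' One line per annotation, ordered by start offset, in the exact layout read
#' by [read_a1()] (the official format of the BioNLP shared tasks).
#'
#' @param anns List of `trig_annotation` objects carrying ids.
#' @param file Output path.
#' @export
write_a1 <- function(anns, file) {
  if (length(anns))
    anns <- anns[order(vapply(anns, function(a) a$start, integer(1)),
                       vapply(anns, function(a) a$end, integer(1)))]
  writeLines(vapply(anns, a1_line, character(1)), file, useBytes = TRUE)
  invisible(anns)
}

## ---- dictionaries ----------------------------------------------------------

#' Read a trigger dictionary from TSV
#'
#' Each line carries two tab-separated fields: an identifier and the list of
#' names for that entry, pipe-separated within the field. Names are
#' whitespace-trimmed; empty names are dropped.
#'
#' @param file Path to the TSV file.
#' @param event_type The trigger type this dictionary tags.
#' @return An object of class `trig_dictionary` with fields `entries`
#'   (named list id -> character vector of names) and `event_type`.
#' @export
read_dictionary_tsv <- function(file, event_type) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  entries <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    if (!nzchar(trimws(raw))) next
    f <- strsplit(raw, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop("parse error at line ", ln, ": expected identifier<TAB>names")
    id <- trimws(f[1L])
    if (id %in% names(entries))
      stop("parse error at line ", ln, ": duplicate identifier ", id)
    names_ <- trimws(strsplit(f[2L], "|", fixed = TRUE)[[1L]])
    entries[[id]] <- names_[nzchar(names_)]
  }
  structure(list(entries = entries, event_type = event_type),
            class = "trig_dictionary")
}

#' Write a trigger dictionary to TSV
#' @param dict A `trig_dictionary`.
#' @param file Output path.
#' @export
write_dictionary_tsv <- function(dict, file) {
  lines <- vapply(names(dict$entries), function(id)
    paste0(id, "\t", paste(dict$entries[[id]], collapse = "|")), character(1))
  writeLines(lines, file, useBytes = TRUE)
  invisible(dict)
}

## ---- trigger output --------------------------------------------------------

#' Write trigger annotations in A1, JSON or XML
#'
#' A1 follows [write_a1()]. JSON is an array of objects with keys `id`,
#' `type`, `start`, `end`, `text`. XML is a flat `<annotations>` element of
#' `<annotation>` children with the same attributes.
#'
#' @param anns List of `trig_annotation` objects.
#' @param format One of `"a1"`, `"json"`, `"xml"`.
#' @param file Output path.
#' @export
write_output <- function(anns, format, file) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("a1", "json", "xml"))
    stop("unknown output format \"", paste(format, collapse = ","),
         "\": expected one of a1, json, xml")
  if (length(anns))
    anns <- anns[order(vapply(anns, function(a) a$start, integer(1)),
                       vapply(anns, function(a) a$end, integer(1)))]
  if (format == "a1") return(write_a1(anns, file))
  if (format == "json") {
    recs <- lapply(anns, function(a)
      list(id = a$id, type = a$type, start = a$start, end = a$end, text = a$text))
    jsonlite::write_json(recs, file, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(anns))
  }
  root <- xml2::xml_new_root("annotations")
  for (a in anns)
    xml2::xml_add_child(root, "annotation", id = a$id, type = a$type,
                        start = as.character(a$start),
                        end = as.character(a$end), text = a$text)
  xml2::write_xml(root, file)
  invisible(anns)
}

#' Read trigger annotations written by [write_output()]
#' @param file Input path.
#' @param format One of `"a1"`, `"json"`, `"xml"`.
#' @param kind Annotation kind to assign (default `"trigger"`).
#' @return List of `trig_annotation` objects.
#' @export
read_output <- function(file, format, kind = "trigger") {
  if (format == "a1") return(read_a1(file, kind = kind))
  if (format == "json") {
    recs <- jsonlite::read_json(file)
    return(lapply(recs, function(r)
      annotation(r$id, r$type, r$start, r$end, r$text, kind = kind)))
  }
  if (format == "xml") {
    doc <- xml2::read_xml(file)
    kids <- xml2::xml_find_all(doc, "annotation")
    return(lapply(kids, function(k)
      annotation(xml2::xml_attr(k, "id"), xml2::xml_attr(k, "type"),
                 as.integer(xml2::xml_attr(k, "start")),
                 as.integer(xml2::xml_attr(k, "end")),
                 xml2::xml_attr(k, "text"), kind = kind)))
  }
  stop("unknown output format \"", format, "\"")
}

# next free "T<n>" id given existing annotations
next_annotation_id <- function(anns) {
  nums <- suppressWarnings(as.integer(sub("^T", "",
    vapply(anns, function(a) if (is.na(a$id)) "T0" else a$id, character(1)))))
  mx <- if (length(nums) && any(!is.na(nums))) max(nums, na.rm = TRUE) else 0L
  mx + 1L
}
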