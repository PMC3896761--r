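# Case-insensitive exact dictionary matching aligned to token boundaries,
# and the two rule-based post-processing filters (odd parentheses, sentences
# without concept annotations).

#' Compile a trigger dictionary into a matcher
#'
#' Names are case-folded once at compile time; matching is case-insensitive
#' exact matching of whole names.
#'
#' @param dict A `trig_dictionary` (see [read_dictionary_tsv()]), or a list
#'   with fields `entries` and `event_type`.
#' @return An object of class `trig_matcher`.
#' @export
compile_dictionary <- function(dict) {
  names_ <- unique(unlist(dict$entries, use.names = FALSE))
  names_ <- names_[nzchar(names_)]
  if (!length(names_)) stop("cannot compile an empty dictionary")
  structure(list(patterns = unique(tolower(names_)),
                 event_type = dict$event_type),
            class = "trig_matcher")
}

#' @export
print.trig_matcher <- function(x, ...) {
  cat(sprintf("<trig_matcher> %s: %d patterns\n", x$event_type,
              length(x$patterns)))
  invisible(x)
}

#' Match a compiled dictionary against a sentence
#'
#' Finds every occurrence of a dictionary name in the sentence text whose
#' both ends coincide with token boundaries (whole-token-span matching, so a
#' name never fires inside a token). Within one dictionary, matches nested
#' inside a longer match are dropped (longest-match preference); distinct
#' dictionaries report independently.
#'
#' @param matcher A `trig_matcher`.
#' @param sentence A `trig_sentence` built with document text available.
#' @return List of unidentified trigger `trig_annotation`s.
#' @export
match_triggers <- function(matcher, sentence) {
  stopifnot(inherits(matcher, "trig_matcher"))
  text <- sentence$text
  if (is.na(text)) stop("sentence carries no text; build it with doc_text")
  folded <- tolower(text)
  starts_ok <- sentence$tokens$start
  ends_ok <- sentence$tokens$end
  hits <- list()
  for (p in matcher$patterns) {
    m <- gregexpr(p, folded, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (k in seq_along(m)) {
      s <- sentence$start + m[k] - 1L            # document offset
      e <- s + attr(m, "match.length")[k]
      if (s %in% starts_ok && e %in% ends_ok)
        hits[[length(hits) + 1L]] <- c(s, e)
    }
  }
  if (!length(hits)) return(list())
  hm <- unique(do.call(rbind, hits))
  keep <- rep(TRUE, nrow(hm))
  for (i in seq_len(nrow(hm))) for (j in seq_len(nrow(hm))) {
    if (i != j && keep[i] &&
        hm[j, 1L] <= hm[i, 1L] && hm[i, 2L] <= hm[j, 2L] &&
        (hm[j, 2L] - hm[j, 1L]) > (hm[i, 2L] - hm[i, 1L]))
      keep[i] <- FALSE                            # nested in a longer match
  }
  hm <- hm[keep, , drop = FALSE]
  hm <- hm[order(hm[, 1L], hm[, 2L]), , drop = FALSE]
  lapply(seq_len(nrow(hm)), function(r) {
    s <- hm[r, 1L]; e <- hm[r, 2L]
    annotation(NA, matcher$event_type, s, e,
               substr(text, s - sentence$start + 1L, e - sentence$start),
               kind = "trigger")
  })
}

#' Remove annotations with unbalanced brackets
#'
#' An annotation whose covered text contains an odd number of round, square
#' or curly bracket characters (each family counted separately) is removed:
#' a dangling bracket indicates a span error by the tagger.
#'
#' @param anns List of `trig_annotation` objects.
#' @return The surviving annotations, unchanged.
#' @export
filter_parentheses <- function(anns) {
  odd_brackets <- function(txt) {
    ch <- strsplit(txt, "")[[1L]]
    fams <- list(c("(", ")"), c("[", "]"), c("{", "}"))
    any(vapply(fams, function(f) sum(ch %in% f) %% 2L == 1L, logical(1)))
  }
  Filter(function(a) !odd_brackets(a$text), anns)
}

#' Remove triggers from sentences without concept annotations
#'
#' Event triggers require an entity to attach to: if a sentence holds no
#' concept annotation, every trigger predicted in it is removed.
#'
#' @param anns List of trigger `trig_annotation`s belonging to `sentence`.
#' @param sentence The `trig_sentence` they were predicted in.
#' @return The surviving annotations, unchanged.
#' @export
filter_no_concept <- function(anns, sentence) {
  has_concept <- length(tree_annotations(sentence$annotations,
                                         kind = "concept")) > 0L
  if (has_concept) anns else list()
}

# apply both rule filters to the trigger annotations of a document
postprocess_document <- function(doc) {
  for (i in seq_along(doc$sentences)) {
    s <- doc$sentences[[i]]
    triggers <- tree_annotations(s$annotations, kind = "trigger")
    kept <- filter_no_concept(filter_parentheses(triggers), s)
    kept_keys <- vapply(kept, function(a)
      paste(a$kind, a$type, a$start, a$end), character(1))
    drop <- Filter(function(a)
      !(paste(a$kind, a$type, a$start, a$end) %in% kept_keys), triggers)
    if (length(drop)) doc <- remove_annotations(doc, drop)
  }
  doc
}
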