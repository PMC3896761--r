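# Exact-match span evaluation with micro-averaged precision, recall and
# F-measure, per event type and per event group, on a 0-100 scale.

#' Event-type grouping presets
#'
#' The conventional grouping of the nine trigger types: `simple` events
#' (gene expression, transcription, protein catabolism, phosphorylation,
#' localization), `binding`, and the `regulation` family.
#' @export
EVENT_GROUPS <- list(
  simple = c("Gene_expression", "Transcription", "Protein_catabolism",
             "Phosphorylation", "Localization"),
  binding = "Binding",
  regulation = c("Regulation", "Positive_regulation", "Negative_regulation")
)

ann_keys <- function(anns) {
  vapply(anns, function(a) paste(a$type, a$start, a$end), character(1))
}

#' Exact-match confusion counts
#'
#' A predicted span is a true positive iff a gold span of the same type has
#' identical start and end offsets (one-to-one matching); unmatched
#' predictions are false positives, unmatched gold spans false negatives.
#'
#' @param gold,pred Lists of `trig_annotation` objects.
#' @return A data frame of class `trig_evalmatrix` with columns `type`,
#'   `TP`, `FP`, `FN`.
#' @export
match_exact <- function(gold, pred) {
  types <- sort(unique(c(vapply(gold, function(a) a$type, character(1)),
                         vapply(pred, function(a) a$type, character(1)))))
  rows <- lapply(types, function(ty) {
    g <- ann_keys(Filter(function(a) a$type == ty, gold))
    p <- ann_keys(Filter(function(a) a$type == ty, pred))
    tp <- 0L
    gt <- table(g)
    for (k in names(table(p))) {
      np <- sum(p == k)
      ng <- if (k %in% names(gt)) gt[[k]] else 0L
      tp <- tp + min(np, ng)
    }
    data.frame(type = ty, TP = tp, FP = length(p) - tp, FN = length(g) - tp,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(type = character(0), TP = integer(0), FP = integer(0),
                  FN = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("trig_evalmatrix", "data.frame")
  out
}

# element-wise sum of matrices (types unioned)
combine_matrices <- function(...) {
  ms <- list(...)
  ms <- Filter(function(m) nrow(m) > 0L, ms)
  if (!length(ms)) return(match_exact(list(), list()))
  all_ <- do.call(rbind, lapply(ms, as.data.frame))
  agg <- stats::aggregate(cbind(TP, FP, FN) ~ type, data = all_, FUN = sum)
  agg <- agg[order(agg$type), ]
  rownames(agg) <- NULL
  class(agg) <- c("trig_evalmatrix", "data.frame")
  agg
}

#' Micro-averaged precision, recall and F-measure
#'
#' Counts are pooled over the requested types before applying
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Empty denominators
#' yield 0. Scores are on a 0-100 scale.
#'
#' @param matrix A `trig_evalmatrix`.
#' @param types Types to pool; default all.
#' @return Named numeric vector `c(P =, R =, F1 =)`.
#' @export
micro_prf <- function(matrix, types = NULL) {
  m <- as.data.frame(matrix)
  if (!is.null(types)) m <- m[m$type %in% types, , drop = FALSE]
  tp <- sum(m$TP); fp <- sum(m$FP); fn <- sum(m$FN)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(P = 100 * p, R = 100 * r, F1 = 100 * f)
}

#' Evaluate predicted triggers against gold triggers
#'
#' Pairs documents by id, pools exact-match counts across the corpus
#' (micro-averaging) and reports per-type, per-group and total scores.
#'
#' @param gold_corpus,pred_corpus `trig_corpus` objects carrying trigger
#'   annotations (gold and predicted respectively).
#' @return An object of class `trig_eval` with fields `matrix` and `scores`.
#' @export
trigger_eval <- function(gold_corpus, pred_corpus) {
  gids <- vapply(gold_corpus, function(d) d$id, character(1))
  pids <- vapply(pred_corpus, function(d) d$id, character(1))
  unpaired <- c(setdiff(gids, pids), setdiff(pids, gids))
  if (length(unpaired))
    warning("skipping unpaired documents: ", paste(unpaired, collapse = ", "))
  common <- intersect(gids, pids)
  mats <- lapply(common, function(id) {
    match_exact(doc_annotations(gold_corpus[[which(gids == id)]], kind = "trigger"),
                doc_annotations(pred_corpus[[which(pids == id)]], kind = "trigger"))
  })
  make_eval(do.call(combine_matrices, mats))
}

# per-type, per-group and total score table from a pooled matrix
make_eval <- function(mat) {
  rows <- list()
  for (ty in mat$type)
    rows[[ty]] <- micro_prf(mat, ty)
  for (g in names(EVENT_GROUPS)) {
    if (any(mat$type %in% EVENT_GROUPS[[g]]))
      rows[[paste0("[", g, "]")]] <- micro_prf(mat, EVENT_GROUPS[[g]])
  }
  rows[["[total]"]] <- micro_prf(mat)
  scores <- do.call(rbind, rows)
  structure(list(matrix = mat, scores = scores), class = "trig_eval")
}

#' @export
print.trig_eval <- function(x, ...) {
  cat("Exact-match micro-averaged evaluation (0-100)\n")
  sc <- x$scores
  cat(sprintf("  %-28s %8s %8s %8s\n", "type", "P", "R", "F1"))
  for (i in seq_len(nrow(sc)))
    cat(sprintf("  %-28s %8.2f %8.2f %8.2f\n", rownames(sc)[i],
                sc[i, "P"], sc[i, "R"], sc[i, "F1"]))
  invisible(x)
}

#' Write an evaluation report as tab-separated values
#' @param ev A `trig_eval`.
#' @param file Output path.
#' @export
write_eval_tsv <- function(ev, file) {
  df <- data.frame(type = rownames(ev$scores), ev$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev)
}
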