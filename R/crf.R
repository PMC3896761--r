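# Per-event-type linear-chain CRF: BIO encoding of trigger spans, the
# composite-label reduction for higher model orders, training by penalized
# maximum conditional likelihood (L-BFGS), Viterbi decoding, and multi-model
# corpus annotation with shared feature extraction.

#' BIO-encode the triggers of one event type
#'
#' Tokens starting a trigger span get `B`, continuation tokens `I`, all
#' others `O`. Overlapping gold spans of the same type are resolved to the
#' longest span before encoding.
#'
#' @param sentence A `trig_sentence` carrying gold trigger annotations.
#' @param event_type The trigger type to encode.
#' @return Character vector of per-token labels.
#' @export
encode_bio <- function(sentence, event_type) {
  n <- n_tokens(sentence)
  labels <- rep("O", n)
  anns <- tree_annotations(sentence$annotations, kind = "trigger",
                           type = event_type)
  if (!length(anns)) return(labels)
  # longest-first; drop spans overlapping an already placed longer span
  ord <- order(-vapply(anns, function(a) a$end - a$start, integer(1)),
               vapply(anns, function(a) a$start, integer(1)))
  taken <- rep(FALSE, n)
  tk <- sentence$tokens
  for (a in anns[ord]) {
    first <- which(tk$start == a$start)
    last <- which(tk$end == a$end)
    if (length(first) != 1L || length(last) != 1L || first > last)
      stop("trigger ", if (is.na(a$id)) a$type else a$id,
           " [", a$start, ",", a$end, ") is not aligned to token boundaries")
    idx <- first:last
    if (any(taken[idx])) next
    taken[idx] <- TRUE
    labels[idx] <- "I"
    labels[first] <- "B"
  }
  labels
}

# BIO label runs -> trigger annotations ("I" after "O" opens a new span)
decode_bio <- function(labels, sentence, event_type) {
  n <- length(labels)
  anns <- list()
  i <- 1L
  while (i <= n) {
    if (labels[i] %in% c("B", "I")) {
      j <- i
      while (j < n && labels[j + 1L] == "I") j <- j + 1L
      s <- sentence$tokens$start[i]; e <- sentence$tokens$end[j]
      anns[[length(anns) + 1L]] <- annotation(
        NA, event_type, s, e,
        substr(sentence$text, s - sentence$start + 1L, e - sentence$start),
        kind = "trigger")
      i <- j + 1L
    } else i <- i + 1L
  }
  anns
}

#' Raise a label sequence to a higher-order composite chain
#'
#' For order `o`, each position's label becomes the concatenation (separator
#' `|`) of the previous `min(o - 1, position - 1)` labels and its own, which
#' reduces an order-`o` chain to a first-order-equivalent one. `o = 1` is the
#' identity.
#'
#' @param labels Character vector of per-token labels.
#' @param o Model order (>= 1).
#' @return Character vector of composite labels.
#' @export
raise_order <- function(labels, o) {
  if (!is.numeric(o) || o < 1L) stop("model order must be >= 1")
  o <- as.integer(o)
  if (o == 1L || !length(labels)) return(labels)
  vapply(seq_along(labels), function(t)
    paste(labels[max(1L, t - o + 1L):t], collapse = "|"), character(1))
}

#' Lower a composite label sequence back to plain labels
#' @param labels Composite labels produced by [raise_order()].
#' @return Character vector of plain labels (the last component of each).
#' @export
lower_order <- function(labels) sub("^.*\\|", "", labels)

label_components <- function(lab) strsplit(lab, "|", fixed = TRUE)[[1L]]

# transition structure of the composite alphabet: cur's prefix must equal
# prev's suffix, and composite length must grow by one until it reaches o
composite_masks <- function(alphabet, o) {
  L <- length(alphabet)
  comps <- lapply(alphabet, label_components)
  lens <- lengths(comps)
  init_ok <- lens == 1L
  trans_ok <- matrix(FALSE, L, L)
  for (p in seq_len(L)) for (l in seq_len(L)) {
    lc <- comps[[l]]; pc <- comps[[p]]
    if (lens[l] != min(o, lens[p] + 1L)) next
    k <- lens[l] - 1L
    if (k == 0L || identical(lc[seq_len(k)], pc[seq.int(lens[p] - k + 1L, lens[p])]))
      trans_ok[p, l] <- TRUE
  }
  list(init_ok = init_ok, trans_ok = trans_ok)
}

# sentence -> integer feature-id vectors per token (unknowns dropped)
index_features <- function(instance, feat_index, bias_id) {
  unseen <- 0L; total <- 0L
  out <- lapply(instance, function(strs) {
    ids <- feat_index[strs]
    total <<- total + length(strs)
    unseen <<- unseen + sum(is.na(ids))
    c(bias_id, sort(unname(ids[!is.na(ids)])))
  })
  attr(out, "unseen_rate") <- if (total) unseen / total else 0
  out
}

#' Train a trigger-recognition CRF for one event type
#'
#' Fits a linear-chain conditional random field
#' \deqn{p(y \mid x, \lambda) = \frac{1}{Z(x)} \exp \sum_j \lambda_j F_j(y, x)}
#' by maximizing the L2-penalized conditional log-likelihood with L-BFGS.
#' Observations are the feature strings produced by [extract_features()]
#' under `config`; labels are the BIO encoding of the gold triggers of
#' `config$event_type`, raised to composite labels when `config$order > 1`.
#' Training is deterministic given the data and hyper-parameters.
#'
#' @param corp A `trig_corpus` (or single `trig_document`) whose sentences
#'   carry gold trigger annotations.
#' @param config A `trig_config` naming the event type and feature set.
#' @param dictionaries Dictionaries for the `dictionary` feature family.
#' @param variance Variance of the Gaussian prior on the weights (default 1).
#' @param maxit Maximum L-BFGS iterations (default 200).
#' @param reltol Convergence tolerance on the objective (default 1e-5).
#' @return A fitted model of class `trig_crf`.
#' @export
crf_train <- function(corp, config, dictionaries = list(),
                      variance = 1.0, maxit = 200L, reltol = 1e-5) {
  stopifnot(inherits(config, "trig_config"))
  if (inherits(corp, "trig_document")) corp <- corpus(list(corp))
  seq_feats_str <- list(); seq_labels_str <- list()
  n_pos <- 0L
  for (doc in corp) for (s in doc$sentences) {
    inst <- extract_features(s, config, dictionaries)
    lab <- encode_bio(s, config$event_type)
    n_pos <- n_pos + sum(lab == "B")
    seq_feats_str[[length(seq_feats_str) + 1L]] <- inst
    seq_labels_str[[length(seq_labels_str) + 1L]] <- raise_order(lab, config$order)
  }
  if (!length(seq_feats_str)) stop("empty corpus")
  if (n_pos == 0L)
    warning("no gold ", config$event_type,
            " spans in the training data; the model will be degenerate")

  feat_alpha <- unique(c("__BIAS__", unlist(seq_feats_str, use.names = FALSE)))
  feat_index <- setNames(seq_along(feat_alpha), feat_alpha)
  bias_id <- 1L
  # composite alphabet: all composites reachable from BIO under order o
  base <- c("O", "B", "I")
  label_alpha <- unique(c(
    unlist(lapply(seq_len(config$order), function(k)
      apply(expand.grid(rep(list(base), k), stringsAsFactors = FALSE), 1L,
            paste, collapse = "|"))),
    unlist(seq_labels_str, use.names = FALSE)))
  masks <- composite_masks(label_alpha, config$order)
  label_index <- setNames(seq_along(label_alpha), label_alpha)

  seqs <- lapply(seq_feats_str, index_features, feat_index = feat_index,
                 bias_id = bias_id)
  labs <- lapply(seq_labels_str, function(l) unname(label_index[l]))

  n_feats <- length(feat_alpha); n_labels <- length(label_alpha)
  n_par <- n_feats * n_labels + n_labels * n_labels
  c2 <- 1 / variance
  fn <- function(w) crf_nll_grad(w, seqs, labs, n_feats, n_labels,
                                 masks$trans_ok, masks$init_ok, c2)$nll
  gr <- function(w) crf_nll_grad(w, seqs, labs, n_feats, n_labels,
                                 masks$trans_ok, masks$init_ok, c2)$grad
  fit <- optim(rep(0, n_par), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit,
                              factr = reltol / .Machine$double.eps))
  structure(
    list(event_type = config$event_type, config = config,
         weights = fit$par, feat_alpha = feat_alpha,
         label_alpha = label_alpha, masks = masks,
         n_sentences = length(seqs), n_positive = n_pos,
         nll = fit$value, convergence = fit$convergence),
    class = "trig_crf")
}

#' @export
print.trig_crf <- function(x, ...) {
  cat(sprintf("<trig_crf> %s (order %d): %d features, %d labels, %d sentences, %d gold spans\n",
              x$event_type, x$config$order, length(x$feat_alpha),
              length(x$label_alpha), x$n_sentences, x$n_positive))
  invisible(x)
}

#' @export
summary.trig_crf <- function(object, ...) {
  w <- coef(object)
  top <- head(sort(abs(w), decreasing = TRUE), 10L)
  cat(sprintf("Trigger CRF for %s\n", object$event_type))
  cat(sprintf("  model order:      %d\n", object$config$order))
  cat(sprintf("  feature families: %s\n",
              paste(object$config$features, collapse = ", ")))
  cat(sprintf("  context:          %s\n", object$config$context))
  cat(sprintf("  parameters:       %d (penalized NLL %.3f)\n",
              length(object$weights), object$nll))
  cat("  largest |weights|:\n")
  for (nm in names(top)) cat(sprintf("    %-50s %8.3f\n", nm, w[[nm]]))
  invisible(object)
}

#' @export
coef.trig_crf <- function(object, ...) {
  L <- length(object$label_alpha)
  state_names <- as.vector(outer(object$label_alpha, object$feat_alpha,
                                 function(l, f) paste0(f, "/", l)))
  trans_names <- as.vector(outer(object$label_alpha, object$label_alpha,
                                 function(l, p) paste0(p, ">", l)))
  setNames(object$weights, c(state_names, trans_names))
}

# decode one sentence given a ready feature instance
decode_sentence <- function(model, sentence, instance, quiet = FALSE) {
  feat_index <- setNames(seq_along(model$feat_alpha), model$feat_alpha)
  seq_ <- index_features(instance, feat_index, bias_id = 1L)
  if (!quiet && attr(seq_, "unseen_rate") > 0.5)
    warning(sprintf("%.0f%% of features unseen in training: was this instance extracted with the model's configuration?",
                    100 * attr(seq_, "unseen_rate")))
  vit <- crf_viterbi(model$weights, seq_, length(model$feat_alpha),
                     length(model$label_alpha), model$masks$trans_ok,
                     model$masks$init_ok)
  composite <- model$label_alpha[vit$path]
  decode_bio(lower_order(composite), sentence, model$event_type)
}

#' Predict trigger annotations with a fitted CRF
#'
#' Runs exact Viterbi decoding of the most probable label sequence on each
#' sentence and converts maximal B/I runs to character-offset trigger
#' annotations typed with the model's event type.
#'
#' @param object A `trig_crf`.
#' @param newdata A `trig_sentence`, `trig_document` or `trig_corpus`.
#' @param dictionaries Dictionaries for the `dictionary` feature family.
#' @param type `"annotations"` (default) or `"labels"` (per-sentence BIO).
#' @param ... Unused.
#' @return For `"annotations"`: a list of `trig_annotation`s (flat across
#'   sentences). For `"labels"`: a list of per-sentence label vectors.
#' @export
predict.trig_crf <- function(object, newdata, dictionaries = list(),
                             type = c("annotations", "labels"), ...) {
  type <- match.arg(type)
  sentences <- if (inherits(newdata, "trig_sentence")) list(newdata)
  else if (inherits(newdata, "trig_document")) newdata$sentences
  else unlist(lapply(newdata, function(d) d$sentences), recursive = FALSE)
  out_ann <- list(); out_lab <- list()
  for (s in sentences) {
    inst <- extract_features(s, object$config, dictionaries)
    anns <- decode_sentence(object, s, inst)
    if (type == "labels") {
      lab <- rep("O", n_tokens(s))
      for (a in anns) {
        idx <- which(s$tokens$start >= a$start & s$tokens$end <= a$end)
        lab[idx] <- "I"; lab[idx[1L]] <- "B"
      }
      out_lab[[length(out_lab) + 1L]] <- lab
    } else out_ann <- c(out_ann, anns)
  }
  if (type == "labels") out_lab else out_ann
}

#' Annotate a corpus with several per-type models
#'
#' Features are extracted once per sentence under the union of the models'
#' configurations ([union_configs()]) and filtered per model, so expensive
#' families are computed a single time however many models run. Every
#' model's spans are inserted into the sentence annotation trees (a token
#' may be a trigger of several event types), then the rule-based
#' post-processing filters are applied.
#'
#' @param models List of `trig_crf` objects.
#' @param corp A `trig_corpus`.
#' @param dictionaries Dictionaries for the `dictionary` feature family.
#' @param postprocess Apply [filter_parentheses()] and [filter_no_concept()]
#'   (default `TRUE`).
#' @return The corpus with predicted trigger annotations inserted.
#' @export
annotate_corpus <- function(models, corp, dictionaries = list(),
                            postprocess = TRUE) {
  if (!length(models)) return(corp)
  uni <- union_configs(lapply(models, function(m) m$config))
  for (di in seq_along(corp)) {
    doc <- corp[[di]]
    existing <- doc_annotations(doc)
    next_id <- next_annotation_id(existing)
    for (si in seq_along(doc$sentences)) {
      s <- doc$sentences[[si]]
      inst <- extract_base(s, uni, dictionaries)
      for (m in models) {
        filtered <- filter_features(inst, s, m$config)
        for (a in decode_sentence(m, s, filtered)) {
          a$id <- paste0("T", next_id); next_id <- next_id + 1L
          doc$sentences[[si]]$annotations <-
            insert_annotation(doc$sentences[[si]]$annotations, a)
        }
      }
    }
    if (postprocess) doc <- postprocess_document(doc)
    corp[[di]] <- doc
  }
  corp
}

#' Save a fitted model bundle
#'
#' The bundle carries the weights, alphabets, masks and the model
#' configuration; [load_model()] restores a model with bit-identical
#' predictions.
#'
#' @param model A `trig_crf`.
#' @param path File path (conventionally `<event_type>.crf`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trig_crf"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a fitted model bundle saved by [save_model()]
#' @param path File path.
#' @return A `trig_crf`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "trig_crf"))
  m
}
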