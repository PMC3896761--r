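# Greedy per-event-type optimization of model configurations: a forward
# pass over feature families, then context selection, then n-gram, hop and
# vertex refinement, each trial evaluated on a held-out development split
# across all candidate model orders.

#' Define an optimization search space
#'
#' @param types Event types to optimize (must have gold spans in the corpus).
#' @param features Ordered feature-family candidates for the greedy pass.
#' @param orders Candidate CRF model orders.
#' @param contexts Candidate context modes (the default before optimization
#'   is `"none"`).
#' @param ngram_sizes List of candidate n-gram size sets (integer vectors).
#' @param hops Candidate dependency-hop limits.
#' @param vertex Candidate vertex feature types.
#' @return An object of class `trig_space`.
#' @export
optimization_space <- function(types,
                               features = FEATURE_FAMILIES,
                               orders = 1L,
                               contexts = CONTEXT_MODES,
                               ngram_sizes = list(c(2L), c(2L, 3L), c(2L, 3L, 4L)),
                               hops = c(1L, 2L, 3L),
                               vertex = VERTEX_TYPES) {
  if (!length(types) || !length(features) || !length(orders))
    stop("optimization space requires non-empty types, features and orders")
  bad <- setdiff(features, FEATURE_FAMILIES)
  if (length(bad)) stop("unknown feature family: ", paste(bad, collapse = ", "))
  structure(list(types = types, features = features,
                 orders = as.integer(orders), contexts = contexts,
                 ngram_sizes = lapply(ngram_sizes, as.integer),
                 hops = as.integer(hops), vertex = vertex),
            class = "trig_space")
}

#' Split a corpus into train and development parts
#'
#' Document-level random partition (sentences of one document never straddle
#' the split), reproducible under `seed`.
#'
#' @param corp A `trig_corpus` of at least two documents.
#' @param ratio Fraction of documents in the train part, in (0,1).
#' @param seed Integer seed.
#' @return List with `trig_corpus` elements `train` and `dev`.
#' @export
split_corpus <- function(corp, ratio = 0.75, seed = 1L) {
  n <- length(corp)
  if (n < 2L) stop("need at least 2 documents to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0,1)")
  k <- min(n - 1L, max(1L, round(ratio * n)))
  idx <- with_seed(seed, sample.int(n, k))
  list(train = corpus(unclass(corp)[sort(idx)]),
       dev = corpus(unclass(corp)[sort(setdiff(seq_len(n), idx))]))
}

# gold triggers of one type, per document
gold_of_type <- function(corp, type) {
  lapply(corp, function(d) doc_annotations(d, kind = "trigger", type = type))
}

# dev micro-F1 of a model for its own event type
dev_f1 <- function(model, dev, dictionaries, return_pred = FALSE) {
  mat <- match_exact(list(), list())
  preds <- list()
  for (d in dev) {
    gold <- doc_annotations(d, kind = "trigger", type = model$event_type)
    pred <- predict(model, d, dictionaries = dictionaries)
    mat <- combine_matrices(mat, match_exact(gold, pred))
    preds[[d$id]] <- pred
  }
  f1 <- unname(micro_prf(mat)["F1"])
  if (return_pred) list(f1 = f1, pred = preds, matrix = mat) else f1
}

#' Train one configuration across all candidate orders
#'
#' Trains a model per order on the train part, scores micro-F1 on the
#' development part, and returns the best order (ties broken toward the
#' lowest order).
#'
#' @param train,dev `trig_corpus` parts from [split_corpus()].
#' @param config A `trig_config` (its `order` field is overridden per trial).
#' @param orders Integer vector of candidate orders.
#' @param dictionaries,... Passed to [crf_train()].
#' @return List with `f1_by_order`, `best_f1`, `best_order` and `dev_pred`
#'   (predictions of the best model on the dev part).
#' @export
train_models <- function(train, dev, config, orders, dictionaries = list(), ...) {
  best <- list(f1 = -Inf, order = NA_integer_, pred = NULL)
  f1s <- setNames(numeric(length(orders)), orders)
  for (o in sort(orders)) {
    cfg <- config; cfg$order <- as.integer(o)
    m <- crf_train(train, cfg, dictionaries = dictionaries, ...)
    res <- dev_f1(m, dev, dictionaries, return_pred = TRUE)
    f1s[[as.character(o)]] <- res$f1
    if (res$f1 > best$f1)          # strict: ties keep the lower order
      best <- list(f1 = res$f1, order = as.integer(o), pred = res$pred)
  }
  list(f1_by_order = f1s, best_f1 = best$f1, best_order = best$order,
       dev_pred = best$pred)
}

log_row <- function(type, step, candidate, f1s, best_order, accepted) {
  data.frame(type = type, step = step, candidate = candidate,
             f1_by_order = paste(sprintf("%s:%.3f", names(f1s), f1s),
                                 collapse = ","),
             best_f1 = max(f1s), best_order = best_order,
             accepted = accepted, stringsAsFactors = FALSE)
}

#' Greedy per-type optimization of model configurations
#'
#' For each event type: (a) a greedy forward pass over the feature families
#' in the order given by the space, keeping a family only on strict dev-F1
#' improvement; (b) context-mode selection (default `"none"`); (c) n-gram
#' size refinement for each retained n-gram-bearing family; (d) hop-limit
#' refinement; (e) vertex-information refinement. Families rejected in (a)
#' are skipped in (c)-(e). Every trial trains across all candidate orders;
#' the order accompanying the final configuration is the best order of the
#' last accepted trial.
#'
#' @param corp A `trig_corpus` with gold triggers for the space's types.
#' @param space A `trig_space`.
#' @param ratio Train fraction for [split_corpus()].
#' @param seed Integer seed for the split.
#' @param dictionaries,... Passed to [crf_train()].
#' @return An object of class `trig_opt`: list with `configs` (named list of
#'   `trig_config`) and `log` (trial audit data frame).
#' @export
optimize_triggers <- function(corp, space, ratio = 0.75, seed = 1L,
                              dictionaries = list(), ...) {
  stopifnot(inherits(space, "trig_space"))
  parts <- split_corpus(corp, ratio = ratio, seed = seed)
  logs <- list()
  configs <- list()
  for (type in space$types) {
    n_gold <- sum(lengths(gold_of_type(corp, type)))
    if (n_gold == 0L) {
      warning("no gold spans for type ", type, "; skipped")
      next
    }
    cfg <- trig_config(type, features = character(0),
                       ngram_sizes = list(morphological = c(2L, 3L),
                                          shortest_path = c(2L, 3L)),
                       hops = list(shortest_path = 3L, dependency_window = 3L),
                       vertex = list(shortest_path = "lemma"),
                       order = min(space$orders))
    best_f1 <- 0
    last_order <- min(space$orders)
    trial <- function(candidate_cfg, step, candidate) {
      tm <- train_models(parts$train, parts$dev, candidate_cfg, space$orders,
                         dictionaries = dictionaries, ...)
      improved <- tm$best_f1 > best_f1
      logs[[length(logs) + 1L]] <<- log_row(type, step, candidate,
                                            tm$f1_by_order, tm$best_order,
                                            improved)
      if (improved) {
        best_f1 <<- tm$best_f1
        last_order <<- tm$best_order
      }
      improved
    }
    # (a) greedy forward pass over families
    for (fam in space$features) {
      cand <- cfg; cand$features <- c(cfg$features, fam)
      if (trial(cand, "feature", fam)) cfg <- cand
    }
    # (b) context selection
    for (ctx in setdiff(space$contexts, "none")) {
      cand <- cfg; cand$context <- ctx
      if (trial(cand, "context", ctx)) cfg <- cand
    }
    # (c) n-gram sizes for retained n-gram-bearing families
    for (fam in intersect(NGRAM_FAMILIES, cfg$features)) {
      for (ns in space$ngram_sizes) {
        if (identical(sort(ns), sort(cfg$ngram_sizes[[fam]]))) next
        cand <- cfg; cand$ngram_sizes[[fam]] <- ns
        if (trial(cand, paste0("ngram:", fam),
                  paste0("{", paste(ns, collapse = ","), "}"))) cfg <- cand
      }
    }
    # (d) hop limits for retained hop-bearing families
    for (fam in intersect(HOP_FAMILIES, cfg$features)) {
      for (h in space$hops) {
        if (h == cfg$hops[[fam]]) next
        cand <- cfg; cand$hops[[fam]] <- h
        if (trial(cand, paste0("hops:", fam), as.character(h))) cfg <- cand
      }
    }
    if (cfg$context == "dependency_window") {
      for (h in space$hops[space$hops <= 3L]) {
        if (h == cfg$hops$dependency_window) next
        cand <- cfg; cand$hops$dependency_window <- h
        if (trial(cand, "hops:dependency_window", as.character(h))) cfg <- cand
      }
    }
    # (e) vertex information for retained vertex-bearing families
    for (fam in intersect(VERTEX_FAMILIES, cfg$features)) {
      for (vt in space$vertex) {
        if (identical(vt, cfg$vertex[[fam]])) next
        cand <- cfg; cand$vertex[[fam]] <- vt
        if (trial(cand, paste0("vertex:", fam), vt)) cfg <- cand
      }
    }
    cfg$order <- last_order
    configs[[type]] <- cfg
  }
  structure(list(configs = configs,
                 log = if (length(logs)) do.call(rbind, logs)
                       else data.frame(),
                 ratio = ratio, seed = seed),
            class = "trig_opt")
}

#' @export
print.trig_opt <- function(x, ...) {
  cat(sprintf("<trig_opt> %d optimized configurations, %d trials (split ratio %.2f, seed %d)\n",
              length(x$configs), nrow(x$log), x$ratio, x$seed))
  for (ty in names(x$configs)) {
    cfg <- x$configs[[ty]]
    acc <- x$log[x$log$type == ty & x$log$accepted, , drop = FALSE]
    cat(sprintf("  %-22s order %d, context %-17s families: %s (dev F1 %.2f)\n",
                ty, cfg$order, cfg$context,
                paste(cfg$features, collapse = ","),
                if (nrow(acc)) max(acc$best_f1) else 0))
  }
  invisible(x)
}

#' Write the optimization trial log as tab-separated values
#' @param opt A `trig_opt`.
#' @param file Output path.
#' @export
write_trial_log <- function(opt, file) {
  utils::write.table(opt$log, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(opt)
}

#' Train final models on the full corpus
#'
#' Retrains each type's model with its optimized configuration on the
#' complete data set and optionally stores one bundle per type.
#'
#' @param corp The full training `trig_corpus`.
#' @param configs Named list of `trig_config` objects (e.g. from
#'   [optimize_triggers()]`$configs`).
#' @param models_dir Optional directory for `<event_type>.crf` bundles.
#' @param dictionaries,... Passed to [crf_train()].
#' @return Named list of `trig_crf` models.
#' @export
finalize_models <- function(corp, configs, models_dir = NULL,
                            dictionaries = list(), ...) {
  models <- list()
  for (ty in names(configs)) {
    m <- crf_train(corp, configs[[ty]], dictionaries = dictionaries, ...)
    models[[ty]] <- m
    if (!is.null(models_dir)) {
      dir.create(models_dir, showWarnings = FALSE, recursive = TRUE)
      save_model(m, file.path(models_dir, paste0(ty, ".crf")))
    }
  }
  models
}
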