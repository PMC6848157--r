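tokenize_levels <- function(records, levels, level_mode = "kmer",
                            base_word_length = 10L) {
  lapply(stats::setNames(levels, levels), function(n) {
    if (level_mode == "kmer") {
      corpus_sentences(records, n)
    } else {
      ## alternative reading: fixed word length, level realized as the
      ## subword gram size inside the embedding
      corpus_sentences(records, base_word_length)
    }
  })
}

level_config <- function(embed_config, level, level_mode) {
  if (level_mode == "kmer") return(embed_config)
  cfg <- embed_config
  cfg$minn <- as.integer(level)
  cfg$maxn <- as.integer(level)
  cfg
}

#' Train one embedding model per n-gram level
#'
#' @param dataset A labeled `prom_dataset` (labels are used only by the
#'   supervised objective).
#' @param levels Integer n-gram levels (default 1:10).
#' @param embed_config Base [embedding_config()]; each level trains with
#'   `seed = embed_config$seed + level`.
#' @param level_mode `"kmer"` (default; level = k-mer word length) or
#'   `"gram_size"` (fixed word length, level = subword gram size).
#' @return Named list of `embedding_model`s.
#' @export
train_level_embeddings <- function(dataset, levels = 1:10,
                                   embed_config = embedding_config(),
                                   level_mode = c("kmer", "gram_size")) {
  level_mode <- match.arg(level_mode)
  sentences <- tokenize_levels(dataset, levels, level_mode)
  labels <- if (embed_config$objective == "supervised") dataset$label else NULL
  models <- lapply(levels, function(n) {
    cfg <- level_config(embed_config, n, level_mode)
    cfg$seed <- embed_config$seed + as.integer(n)
    train_embedding(sentences[[as.character(n)]], labels = labels,
                    config = cfg, level = n)
  })
  names(models) <- levels
  models
}

#' Featurize sequences with trained per-level embeddings
#'
#' Tokenizes each record at every level, reduces each sentence with
#' [sequence_vector()], and concatenates the per-level blocks with
#' [combine_features()].
#'
#' @param records A `prom_dataset` (or data frame of `id`/`bases`).
#' @param models Named list of per-level `embedding_model`s (as from
#'   [train_level_embeddings()]).
#' @param level_mode As in [train_level_embeddings()].
#' @return A [feature_table()] when `records` carries labels, otherwise
#'   a bare combined matrix with a `layout` attribute.
#' @export
featurize_dataset <- function(records, models,
                              level_mode = c("kmer", "gram_size")) {
  level_mode <- match.arg(level_mode)
  levels <- as.integer(names(models))
  sentences <- tokenize_levels(records, levels, level_mode)
  blocks <- lapply(stats::setNames(levels, levels), function(n) {
    sequence_vectors(sentences[[as.character(n)]], models[[as.character(n)]])
  })
  combined <- combine_features(blocks)
  if (!is.null(records$label) && !anyNA(records$label)) {
    tab <- dataset_feature_table(records, combined)
    attr(tab$x, "layout") <- attr(combined, "layout")
    tab
  } else {
    combined
  }
}

#' Repeated cross-validation of the full promoter pipeline
#'
#' Runs the complete protocol on raw sequences: tokenize at the chosen
#' levels, train per-level embeddings, combine sequence vectors,
#' optionally keep the top MRMD-ranked features, and classify with the
#' 1D CNN (or the kNN baseline) under stratified 5-fold cross-validation
#' repeated `n_repeats` times.  By default embeddings (and MRMD) are fit
#' on each training fold only, so no label or feature information leaks
#' into validation folds; `global_mode = TRUE` instead fits the
#' embeddings once per repeat on the full dataset, reproducing the
#' protocol in which features are extracted globally before
#' cross-validation.
#'
#' @param dataset A labeled `prom_dataset`.
#' @param levels Integer n-gram levels (default 1:10).
#' @param embed_config Base [embedding_config()].
#' @param model `"cnn"` or `"knn"`.
#' @param cnn Named list of overrides for [cnn_config()] (e.g.
#'   `list(epochs = 30)`).
#' @param knn_k Neighbours for the kNN baseline.
#' @param mrmd_k Optional integer: keep this many top MRMD features
#'   (ranked on the training portion; on the full table in global mode).
#' @param n_folds,n_repeats Plan size.
#' @param compare_levels Also train one CNN per single n-gram level on
#'   that level's block of the combined features (sharing the fold's
#'   embeddings) and record its validation AUC; results appear in the
#'   `level_auc` attribute.  CNN model only.
#' @param global_mode Fit embeddings (and MRMD) globally instead of per
#'   training fold.
#' @param level_mode As in [train_level_embeddings()].
#' @param seed Base seed for folds, embeddings and model training.
#' @return Per-repeat per-fold metrics data frame (see [cv_table()])
#'   with `summary` and `manifest` attributes.
#' @export
promoter_cv <- function(dataset, levels = 1:10,
                        embed_config = embedding_config(),
                        model = c("cnn", "knn"), cnn = list(), knn_k = 10L,
                        mrmd_k = NULL, n_folds = 5L, n_repeats = 1L,
                        compare_levels = FALSE, global_mode = FALSE,
                        level_mode = c("kmer", "gram_size"), seed = 1L) {
  model <- match.arg(model)
  level_mode <- match.arg(level_mode)
  stopifnot(inherits(dataset, "prom_dataset"))
  labels <- dataset$label
  if (length(unique(labels)) < 2L) stop("dataset has a single class", call. = FALSE)
  positive <- positive_class(attr(dataset, "layer"))
  sentences <- tokenize_levels(dataset, levels, level_mode)

  fit_embeddings <- function(idx, eseed) {
    models <- lapply(levels, function(n) {
      cfg <- level_config(embed_config, n, level_mode)
      cfg$seed <- eseed + as.integer(n)
      train_embedding(sentences[[as.character(n)]][idx],
                      labels = if (cfg$objective == "supervised") labels[idx] else NULL,
                      config = cfg, level = n)
    })
    names(models) <- levels
    models
  }
  features_for <- function(models, idx) {
    blocks <- lapply(stats::setNames(levels, levels), function(n) {
      sequence_vectors(sentences[[as.character(n)]][idx],
                       models[[as.character(n)]])
    })
    combine_features(blocks)
  }
  fit_classifier <- function(x, y, cseed) {
    tab <- feature_table(x, y, positive = positive)
    if (model == "cnn") {
      cfg <- do.call(cnn_config, modifyList(list(input_dim = ncol(x), seed = cseed),
                                            cnn))
      train_cnn(build_cnn(cfg), tab)
    } else {
      tab
    }
  }
  score_classifier <- function(fitted, x, y_train_tab = NULL) {
    if (model == "cnn") {
      predict(fitted, x, type = "prob")[, 2L]
    } else {
      std <- standardize_columns(fitted$x)
      xs <- sweep(sweep(x, 2L, std$center, "-"), 2L, std$scale, "/")
      knn_predict(std$x, fitted$labels, xs, k = knn_k,
                  positive = fitted$positive)$score
    }
  }

  rows <- list()
  level_rows <- list()
  sorted_levels <- sort(as.integer(levels))
  for (r in seq_len(n_repeats)) {
    rseed <- as.integer(seed) + 7919L * (r - 1L)
    folds <- make_folds(labels, n_folds = n_folds, seed = rseed)
    global_models <- if (global_mode) fit_embeddings(seq_along(labels), rseed) else NULL
    global_features <- if (global_mode) features_for(global_models, seq_along(labels)) else NULL
    global_keep <- NULL
    if (global_mode && !is.null(mrmd_k)) {
      ranking <- mrmd_rank(feature_table(global_features, labels,
                                         positive = positive))
      global_keep <- match(mrmd_top(ranking, mrmd_k), colnames(global_features))
    }
    for (f in seq_len(n_folds)) {
      tr_idx <- which(folds != f)
      te_idx <- which(folds == f)
      if (global_mode) {
        x_tr <- global_features[tr_idx, , drop = FALSE]
        x_te <- global_features[te_idx, , drop = FALSE]
        keep <- global_keep
      } else {
        fold_models <- fit_embeddings(tr_idx, rseed + 101L * f)
        x_tr <- features_for(fold_models, tr_idx)
        x_te <- features_for(fold_models, te_idx)
        keep <- NULL
        if (!is.null(mrmd_k)) {
          ranking <- mrmd_rank(feature_table(x_tr, labels[tr_idx],
                                             positive = positive))
          keep <- match(mrmd_top(ranking, mrmd_k), colnames(x_tr))
        }
      }
      if (compare_levels && model == "cnn") {
        dim <- embed_config$dim
        for (li in seq_along(sorted_levels)) {
          cols <- seq.int((li - 1L) * dim + 1L, li * dim)
          fit_l <- fit_classifier(x_tr[, cols, drop = FALSE], labels[tr_idx],
                                  cseed = rseed + f + 513L * li)
          score_l <- score_classifier(fit_l, x_te[, cols, drop = FALSE])
          level_rows[[length(level_rows) + 1L]] <-
            data.frame(repeat_id = r, fold_id = f, level = sorted_levels[li],
                       auc = roc_auc(labels[te_idx], score_l,
                                     positive = positive)$auc)
        }
      }
      if (!is.null(keep)) {
        x_tr <- x_tr[, keep, drop = FALSE]
        x_te <- x_te[, keep, drop = FALSE]
      }
      fitted <- fit_classifier(x_tr, labels[tr_idx], cseed = rseed + f)
      score <- score_classifier(fitted, x_te)
      rows[[length(rows) + 1L]] <- fold_metrics(labels[te_idx], score, positive,
                                                repeat_id = r, fold_id = f)
    }
  }
  res <- finish_cv(rows)
  if (length(level_rows) > 0L) {
    attr(res, "level_auc") <- do.call(rbind, level_rows)
  }
  attr(res, "manifest") <- list(levels = levels, model = model,
                                objective = embed_config$objective,
                                embed_epochs = embed_config$epoch,
                                dim = embed_config$dim, cnn = cnn,
                                knn_k = knn_k, mrmd_k = mrmd_k,
                                n_folds = n_folds, n_repeats = n_repeats,
                                global_mode = global_mode,
                                level_mode = level_mode, seed = seed)
  res
}

#' Fit the full promoter model on a labeled dataset
#'
#' Trains per-level embeddings and the combined-feature CNN on the whole
#' dataset, for later prediction on new sequences (optionally as the
#' first stage of a two-layer cascade).
#'
#' @param dataset A labeled `prom_dataset`.
#' @param levels,embed_config,level_mode As in [promoter_cv()].
#' @param cnn Named list of [cnn_config()] overrides.
#' @param mrmd_k Optional number of top MRMD features to keep.
#' @param seed Base seed.
#' @return A `promoter_model`.
#' @export
promoter_fit <- function(dataset, levels = 1:10,
                         embed_config = embedding_config(), cnn = list(),
                         mrmd_k = NULL, level_mode = c("kmer", "gram_size"),
                         seed = 1L) {
  level_mode <- match.arg(level_mode)
  cfg <- embed_config
  cfg$seed <- as.integer(seed)
  embeddings <- train_level_embeddings(dataset, levels, cfg, level_mode)
  table <- featurize_dataset(dataset, embeddings, level_mode)
  keep <- NULL
  if (!is.null(mrmd_k)) {
    ranking <- mrmd_rank(table)
    keep <- mrmd_top(ranking, mrmd_k)
    table <- subset_table(table, cols = match(keep, table$feature_names))
  }
  cnn_cfg <- do.call(cnn_config,
                     modifyList(list(input_dim = ncol(table$x),
                                     seed = as.integer(seed)), cnn))
  net <- train_cnn(build_cnn(cnn_cfg), table)
  structure(list(layer = attr(dataset, "layer"), levels = levels,
                 embed_config = cfg, level_mode = level_mode,
                 embeddings = embeddings, keep = keep, cnn = net,
                 positive = table$positive, seed = as.integer(seed)),
            class = "promoter_model")
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf("<promoter_model> %s, levels %s, %d features -> CNN\n",
              x$layer, paste(range(x$levels), collapse = "-"),
              x$cnn$config$input_dim))
  invisible(x)
}

#' Predict classes for new sequences
#'
#' @param object A `promoter_model` from [promoter_fit()].
#' @param records A data frame of `id`/`bases` (labels ignored).
#' @param layer2 Optional second-stage `promoter_model` (strong vs
#'   weak); when given, layer-1 positives are forwarded to it and calls
#'   are in non-promoter/weak/strong.
#' @param ... Unused.
#' @return Data frame with `id`, the class probabilities and `call`.
#' @export
predict.promoter_model <- function(object, records, layer2 = NULL, ...) {
  if (nrow(records) == 0L) {
    warning("empty input; returning empty prediction")
    return(data.frame(id = character(), p_neg = numeric(), p_pos = numeric(),
                      call = character()))
  }
  x <- featurize_records(object, records)
  probs <- predict(object$cnn, x, type = "prob")
  call <- ifelse(probs[, 2L] >= probs[, 1L], colnames(probs)[2L],
                 colnames(probs)[1L])
  out <- data.frame(id = records$id, p_neg = probs[, 1L], p_pos = probs[, 2L],
                    call = call, stringsAsFactors = FALSE)
  if (!is.null(layer2)) {
    fwd <- which(out$call == object$positive)
    if (length(fwd) > 0L) {
      second <- predict(layer2, records[fwd, , drop = FALSE])
      out$call[fwd] <- second$call
      out$p_strong <- NA_real_
      out$p_strong[fwd] <- second$p_pos
    }
  }
  out
}

featurize_records <- function(object, records) {
  unlabeled <- records[, c("id", "bases"), drop = FALSE]
  x <- featurize_dataset(unlabeled, object$embeddings, object$level_mode)
  if (!is.null(object$keep)) x <- x[, object$keep, drop = FALSE]
  x
}
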