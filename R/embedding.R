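#' Configuration for subword-aware embedding training
#'
#' Defaults follow the tuned optimum for this pipeline: learning rate
#' 0.1, vector dimension 100, context window 5, 100 epochs, softmax loss,
#' supervised objective.  Character n-grams of sizes `minn..maxn`
#' (clipped to the boundary-wrapped word) plus the whole-word token make
#' up each word's subword set.
#'
#' @param dim Vector dimension (default 100).
#' @param lr Initial learning rate (default 0.1; decays linearly to 0).
#' @param ws Context window size for skipgram/cbow (default 5).
#' @param epoch Training passes over the corpus (default 100).
#' @param loss One of `"softmax"`, `"ns"`, `"hs"`.  The supervised head
#'   has two classes, for which all three reduce to the same exact
#'   softmax update; unsupervised objectives use negative sampling.
#' @param objective `"supervised"` (class prediction from averaged input
#'   vectors), `"skipgram"` or `"cbow"`.
#' @param minn,maxn Character n-gram size bounds (defaults 3 and 6).
#' @param neg Negative samples per positive pair (unsupervised only).
#' @param seed Integer seed; training is single-threaded and
#'   deterministic given the seed.
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(dim = 100, lr = 0.1, ws = 5, epoch = 100,
                             loss = c("softmax", "ns", "hs"),
                             objective = c("supervised", "skipgram", "cbow"),
                             minn = 3, maxn = 6, neg = 5, seed = 1L) {
  loss <- match.arg(loss)
  objective <- match.arg(objective)
  stopifnot(dim >= 1, lr > 0, epoch >= 1, ws >= 1, minn >= 1, neg >= 1)
  if (minn > maxn) stop("minn must be <= maxn", call. = FALSE)
  structure(list(dim = as.integer(dim), lr = lr, ws = as.integer(ws),
                 epoch = as.integer(epoch), loss = loss, objective = objective,
                 minn = as.integer(minn), maxn = as.integer(maxn),
                 neg = as.integer(neg), seed = as.integer(seed)),
            class = "embedding_config")
}

#' Character n-grams of a boundary-wrapped word
#'
#' The word is wrapped in the boundary symbols `<` and `>`, all character
#' n-grams with sizes in `minn..maxn` are extracted from the wrapped
#' form, and the whole-word token (the wrapped word itself) is always
#' included.  Because of the boundary symbols, the whole-word token
#' `<TGA>` of the word "TGA" is distinct from the interior tri-gram
#' `TGA` extracted from a longer word.
#'
#' @param word Non-empty word string.
#' @param minn,maxn Inclusive n-gram size bounds.
#' @return Character vector (a set: unique tokens) always containing the
#'   whole-word token.
#' @export
char_ngrams <- function(word, minn = 3, maxn = 6) {
  if (!nzchar(word)) stop("word must be non-empty", call. = FALSE)
  if (minn > maxn) stop("minn must be <= maxn", call. = FALSE)
  wrapped <- paste0("<", word, ">")
  L <- nchar(wrapped)
  grams <- character()
  hi <- min(maxn, L)
  if (minn <= hi) {
    for (size in seq.int(minn, hi)) {
      starts <- seq_len(L - size + 1L)
      grams <- c(grams, substring(wrapped, starts, starts + size - 1L))
    }
  }
  unique(c(grams, wrapped))
}

## split a flat vector back into groups of the given lengths, preserving
## group order (split() alone would order integer groups as characters)
relist_by_lengths <- function(flat, lens) {
  out <- split(flat, factor(rep.int(seq_along(lens), lens),
                            levels = seq_along(lens)))
  names(out) <- NULL
  out
}

build_subword_vocab <- function(sentences, minn, maxn) {
  words <- unique(unlist(sentences, use.names = FALSE))
  if (length(words) == 0L) stop("empty corpus", call. = FALSE)
  gram_sets <- lapply(words, char_ngrams, minn = minn, maxn = maxn)
  flat <- unlist(gram_sets, use.names = FALSE)
  grams <- unique(flat)
  ## one global match, then refold per word (a match per word would
  ## rebuild the hash table tens of thousands of times)
  idx <- match(flat, grams)
  word_gram_ids <- relist_by_lengths(idx, lengths(gram_sets))
  list(words = words, grams = grams, word_gram_ids = word_gram_ids)
}

#' Train a subword-aware embedding model on tokenized sentences
#'
#' The supervised objective learns to predict each sentence's class from
#' the average of its subword input vectors (the training-time analogue
#' of [sequence_vector()]); skipgram and cbow optimize
#' word-in-context scores with negative sampling.  The subword dictionary
#' is exact — every character n-gram over A/C/G/T/N gets its own vector,
#' no hash buckets — so training is bit-reproducible given the seed.
#'
#' @param sentences List of word vectors (see [corpus_sentences()]).
#' @param labels Binary labels, one per sentence; required iff
#'   `objective = "supervised"`.
#' @param config An [embedding_config()].
#' @param level Optional n-gram level tag stored on the model.
#' @return An `embedding_model` with per-gram input vectors, context (or
#'   class) output vectors, and the per-epoch training loss.
#' @export
train_embedding <- function(sentences, labels = NULL,
                            config = embedding_config(), level = NA_integer_) {
  stopifnot(inherits(config, "embedding_config"))
  if (length(sentences) == 0L) stop("empty corpus", call. = FALSE)
  vocab <- build_subword_vocab(sentences, config$minn, config$maxn)
  flat_words <- unlist(sentences, use.names = FALSE)
  flat_ids <- match(flat_words, vocab$words)
  word_ids <- relist_by_lengths(flat_ids, lengths(sentences))
  lens <- lengths(vocab$word_gram_ids)

  if (config$objective == "supervised") {
    if (is.null(labels)) stop("supervised objective requires labels", call. = FALSE)
    if (length(labels) != length(sentences)) {
      stop("one label per sentence required", call. = FALSE)
    }
    classes <- sort(unique(as.character(labels)))
    if (length(classes) < 2L) {
      stop("supervised objective needs both classes present", call. = FALSE)
    }
    y <- match(as.character(labels), classes) - 1L
    bags <- lapply(word_ids, function(wids) {
      W <- length(wids)
      ids <- unlist(vocab$word_gram_ids[wids], use.names = FALSE)
      w <- rep(1 / (W * lens[wids]), lens[wids])
      agg <- rowsum(w, ids)  # collapse repeated grams; h and its gradient are unchanged
      list(ids = as.integer(rownames(agg)) - 1L, w = as.numeric(agg))
    })
    fit <- ft_supervised(lapply(bags, `[[`, "ids"), lapply(bags, `[[`, "w"),
                         y, length(vocab$grams), length(classes),
                         config$dim, config$lr, config$epoch, config$seed)
    context_labels <- classes
  } else {
    if (config$loss == "hs") {
      stop("hierarchical softmax is not implemented for unsupervised objectives; use loss = 'ns'",
           call. = FALSE)
    }
    counts <- tabulate(unlist(word_ids, use.names = FALSE), nbins = length(vocab$words))
    uni <- counts^0.75
    uni <- uni / sum(uni)
    sent0 <- lapply(word_ids, function(x) x - 1L)
    grams0 <- lapply(vocab$word_gram_ids, function(x) x - 1L)
    fit <- if (config$objective == "skipgram") {
      ft_skipgram(sent0, grams0, uni, length(vocab$grams),
                  config$dim, config$lr, config$ws, config$epoch,
                  config$neg, config$seed)
    } else {
      ft_cbow(sent0, grams0, uni, length(vocab$grams),
              config$dim, config$lr, config$ws, config$epoch,
              config$neg, config$seed)
    }
    classes <- NULL
    context_labels <- vocab$words
  }

  structure(list(level = level, config = config,
                 words = vocab$words, grams = vocab$grams,
                 word_gram_ids = vocab$word_gram_ids,
                 input = fit$input, output = fit$output,
                 loss_history = as.numeric(fit$loss),
                 classes = classes, context_labels = context_labels),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> level %s, %s objective: %d words, %d grams, dim %d\n",
              x$level, x$config$objective, length(x$words), length(x$grams),
              x$config$dim))
  invisible(x)
}

#' Word-in-context score (sum of subword dot products)
#'
#' The score of word `w` in context `c` is the sum over the word's gram
#' set of the dot product between each gram's input vector and the
#' context's output vector.  Grams unknown to the model contribute
#' nothing; a word with no known grams scores 0.
#'
#' @param word Word string.
#' @param context Context identifier: a class label for supervised
#'   models, a corpus word for skipgram/cbow models.
#' @param model An `embedding_model`.
#' @return Numeric scalar.
#' @export
embedding_score <- function(word, context, model) {
  ci <- match(context, model$context_labels)
  if (is.na(ci)) stop(sprintf("unknown context '%s'", context), call. = FALSE)
  gids <- word_gram_lookup(model, word)
  if (length(gids) == 0L) return(0)
  sum(model$input[gids, , drop = FALSE] %*% model$output[ci, ])
}

word_gram_lookup <- function(model, word, word_index = NULL) {
  wi <- word_index %||% match(word, model$words)
  if (!is.na(wi)) return(model$word_gram_ids[[wi]])
  gids <- match(char_ngrams(word, model$config$minn, model$config$maxn),
                model$grams)
  gids[!is.na(gids)]
}

word_representations <- function(model, words) {
  wi <- match(words, model$words)   # one hash build for the whole batch
  gids <- vector("list", length(words))
  in_vocab <- !is.na(wi)
  gids[in_vocab] <- model$word_gram_ids[wi[in_vocab]]
  if (any(!in_vocab)) {
    ## out-of-vocabulary words fall back to their known subword grams
    oov <- which(!in_vocab)
    gsets <- lapply(words[oov], char_ngrams,
                    minn = model$config$minn, maxn = model$config$maxn)
    flat_g <- match(unlist(gsets, use.names = FALSE), model$grams)
    per <- relist_by_lengths(flat_g, lengths(gsets))
    gids[oov] <- lapply(per, function(v) v[!is.na(v)])
  }
  lens <- lengths(gids)
  reps <- matrix(0, nrow = length(words), ncol = model$config$dim)
  known <- lens > 0L
  if (any(known)) {
    ## sparse word-by-gram averaging operator; avoids materializing the
    ## (total grams) x dim expansion
    flat <- unlist(gids[known], use.names = FALSE)
    grp <- rep.int(seq_len(sum(known)), lens[known])
    agg <- Matrix::sparseMatrix(i = grp, j = flat,
                                x = rep.int(1 / lens[known], lens[known]),
                                dims = c(sum(known), nrow(model$input)))
    reps[known, ] <- as.matrix(agg %*% model$input)
  }
  attr(reps, "known") <- known
  reps
}

#' Fixed-length vector for one tokenized sequence
#'
#' A word's representation is the mean of its gram input vectors (the
#' whole-word token included); the sequence vector is the unweighted mean
#' of its words' representations.  Mean aggregation makes the result
#' order-invariant in the word multiset.
#'
#' @param sentence Character vector of words.
#' @param model An `embedding_model`.
#' @return Numeric vector of length `model$config$dim`.
#' @export
sequence_vector <- function(sentence, model) {
  if (length(sentence) == 0L) stop("sentence must be non-empty", call. = FALSE)
  distinct <- unique(sentence)
  reps <- word_representations(model, distinct)
  if (!any(attr(reps, "known"))) {
    warning("no model-known grams in sentence; returning zero vector")
    return(numeric(model$config$dim))
  }
  colMeans(reps[match(sentence, distinct), , drop = FALSE])
}

#' Sequence vectors for a whole corpus
#'
#' @param sentences List of word vectors.
#' @param model An `embedding_model`.
#' @return Matrix, one row per sentence, `model$config$dim` columns.
#' @export
sequence_vectors <- function(sentences, model) {
  distinct <- unique(unlist(sentences, use.names = FALSE))
  reps <- word_representations(model, distinct)
  flat <- match(unlist(sentences, use.names = FALSE), distinct)
  grp <- rep.int(seq_along(sentences), lengths(sentences))
  out <- rowsum(reps[flat, , drop = FALSE], grp, reorder = FALSE) /
    lengths(sentences)
  dimnames(out) <- list(names(sentences), NULL)
  out
}

#' Class probabilities from a supervised embedding model
#'
#' The supervised classifier's own predictions: softmax over class scores
#' of the averaged subword input vectors.
#'
#' @param model A supervised `embedding_model`.
#' @param sentences List of word vectors.
#' @return Matrix of probabilities, one row per sentence, one column per
#'   class (in `model$classes` order).
#' @export
predict_embedding <- function(model, sentences) {
  if (is.null(model$classes)) {
    stop("predict_embedding requires a supervised model", call. = FALSE)
  }
  h <- sequence_vectors(sentences, model)
  scores <- h %*% t(model$output)
  probs <- t(apply(scores, 1L, softmax))
  colnames(probs) <- model$classes
  probs
}

#' Persist an embedding model as plain text
#'
#' Writes `<path>.json` (config header, vocabulary bookkeeping) and
#' `<path>.vec` (one token per line: token then `dim` values, input
#' vectors first, then context vectors).  The pair is loadable without
#' the training corpus via [load_embedding()].
#'
#' @param model An `embedding_model`.
#' @param path Path stem (no extension).
#' @return `path`, invisibly.
#' @export
save_embedding <- function(model, path) {
  header <- list(level = model$level, config = unclass(model$config),
                 words = model$words, grams = model$grams,
                 classes = model$classes, context_labels = model$context_labels,
                 loss_history = model$loss_history)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  fmt <- function(m, tokens) {
    vals <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    paste(tokens, vals)
  }
  writeLines(c(fmt(model$input, model$grams),
               fmt(model$output, paste0("__ctx__", model$context_labels))),
             paste0(path, ".vec"))
  invisible(path)
}

#' Load an embedding model saved by [save_embedding()]
#'
#' @param path Path stem used at save time.
#' @return An `embedding_model`.
#' @export
load_embedding <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lines <- readLines(paste0(path, ".vec"))
  parts <- strsplit(lines, " ", fixed = TRUE)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(parts[[1L]]) - 1L)))
  n_grams <- length(header$grams)
  cfg <- do.call(embedding_config, header$config[c("dim", "lr", "ws", "epoch",
                                                  "loss", "objective", "minn",
                                                  "maxn", "neg", "seed")])
  gram_sets <- lapply(header$words, char_ngrams, minn = cfg$minn, maxn = cfg$maxn)
  structure(list(level = header$level, config = cfg,
                 words = header$words, grams = header$grams,
                 word_gram_ids = lapply(gram_sets, match, table = header$grams),
                 input = vals[seq_len(n_grams), , drop = FALSE],
                 output = vals[-seq_len(n_grams), , drop = FALSE],
                 loss_history = header$loss_history,
                 classes = header$classes,
                 context_labels = header$context_labels),
            class = "embedding_model")
}
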