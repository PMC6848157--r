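#' Concatenate per-level sequence vectors into the combined representation
#'
#' Blocks are concatenated in ascending n-gram level order and the block
#' layout (level, offset, dim) is recorded so that any level's block can
#' be sliced back out losslessly.  With the default ten levels at
#' dimension 100 the combined vector has 1,000 features.
#'
#' @param per_level Named list (names = levels) of numeric vectors, or of
#'   matrices with one row per sample.
#' @param levels Levels that must be present (default: the names found,
#'   sorted numerically).
#' @return A vector (or matrix) with a `layout` attribute and feature
#'   names `feature_1`, `feature_2`, ...
#' @export
combine_features <- function(per_level, levels = NULL) {
  lv <- as.integer(names(per_level))
  if (anyNA(lv)) stop("per_level must be named by integer level", call. = FALSE)
  levels <- levels %||% sort(lv)
  missing <- setdiff(levels, lv)
  if (length(missing) > 0L) {
    stop(sprintf("missing levels: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  ord <- order(lv)
  per_level <- per_level[ord]
  lv <- lv[ord]
  as_mat <- lapply(per_level, function(b) {
    if (is.matrix(b)) b else matrix(b, nrow = 1L)
  })
  dims <- vapply(as_mat, ncol, integer(1L))
  rows <- vapply(as_mat, nrow, integer(1L))
  if (length(unique(dims)) != 1L) {
    stop(sprintf("per-level dimension mismatch: %s", paste(dims, collapse = ", ")),
         call. = FALSE)
  }
  if (length(unique(rows)) != 1L) {
    stop("per-level sample count mismatch", call. = FALSE)
  }
  combined <- do.call(cbind, as_mat)
  layout <- data.frame(level = lv,
                       offset = cumsum(c(0L, dims[-length(dims)])) + 1L,
                       dim = dims)
  colnames(combined) <- paste0("feature_", seq_len(ncol(combined)))
  if (all(rows == 1L) && !is.matrix(per_level[[1L]])) {
    combined <- stats::setNames(drop(combined),
                                paste0("feature_", seq_len(sum(dims))))
  }
  attr(combined, "layout") <- layout
  combined
}

#' Slice one level's block out of a combined representation
#'
#' @param combined Result of [combine_features()].
#' @param level Level to extract.
#' @return The block for that level (vector or matrix), without names.
#' @export
slice_level <- function(combined, level) {
  layout <- attr(combined, "layout")
  if (is.null(layout)) stop("no layout attribute; not a combined vector", call. = FALSE)
  row <- layout[layout$level == level, ]
  if (nrow(row) != 1L) stop(sprintf("level %s not in layout", level), call. = FALSE)
  idx <- seq.int(row$offset, row$offset + row$dim - 1L)
  if (is.matrix(combined)) {
    unname(combined[, idx, drop = FALSE])
  } else {
    unname(combined[idx])
  }
}

standardize_columns <- function(x, center = NULL, scale = NULL) {
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(x = sweep(sweep(x, 2L, center, "-"), 2L, scale, "/"),
       center = center, scale = scale)
}

#' Maximum-Relevance-Maximum-Distance (MRMD) feature ranking
#'
#' Relevance of feature *i* is the absolute Pearson correlation between
#' the (z-standardized) feature and the 0/1 label vector (0 for a
#' constant feature).  Distance is the mean of three dissimilarity
#' components of feature *i* against all other features — Euclidean
#' distance, cosine distance (1 - cosine similarity) and Tanimoto
#' distance (1 - Tanimoto coefficient) — each component min-max scaled to
#' \[0, 1\] across features before averaging.  The total score is
#' relevance + distance, normalized so the top-ranked feature scores
#' exactly 1.0; ties rank by feature index.
#'
#' @param table A [feature_table()] with both classes present and at
#'   least two features.
#' @param standardize Z-standardize features first (default `TRUE`; the
#'   distance components are scale-sensitive).
#' @return An `mrmd_ranking`: data frame with columns `feature`,
#'   `relevance`, `distance`, `score`, `rank` (in original feature
#'   order), with the normalization constant as attribute `norm`.
#' @export
mrmd_rank <- function(table, standardize = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  y <- as.integer(table$labels == table$positive)
  if (length(unique(y)) < 2L) stop("labels must contain both classes", call. = FALSE)
  if (ncol(table$x) < 2L) stop("need at least 2 features", call. = FALSE)
  x <- if (standardize) standardize_columns(table$x)$x else table$x
  p <- ncol(x)

  sdx <- apply(x, 2L, stats::sd)
  mr <- numeric(p)
  ok <- sdx > 0
  if (any(ok)) mr[ok] <- abs(cor(x[, ok, drop = FALSE], y))

  ## pairwise feature-feature components via gram matrix
  g <- crossprod(x)                       # p x p dot products
  sq <- diag(g)
  ed2 <- outer(sq, sq, "+") - 2 * g
  ed2[ed2 < 0] <- 0
  ed <- sqrt(ed2)
  norms <- sqrt(sq)
  denom_cos <- outer(norms, norms)
  cos_sim <- ifelse(denom_cos > 0, g / denom_cos, 0)
  denom_tani <- outer(sq, sq, "+") - g
  tani <- ifelse(denom_tani != 0, g / denom_tani, 0)

  mean_off <- function(m) (rowSums(m) - diag(m)) / (p - 1L)
  comp <- cbind(euclidean = mean_off(ed),
                cosine = mean_off(1 - cos_sim),
                tanimoto = mean_off(1 - tani))
  scale01 <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, length(v))
  }
  md <- rowMeans(apply(comp, 2L, scale01))

  score <- mr + md
  norm <- max(score)
  score <- score / norm
  ord <- order(-score, seq_len(p))
  rank <- integer(p)
  rank[ord] <- seq_len(p)
  structure(data.frame(feature = table$feature_names, relevance = mr,
                       distance = md, score = score, rank = rank,
                       stringsAsFactors = FALSE),
            norm = norm, class = c("mrmd_ranking", "data.frame"))
}

#' Top-k feature names of an MRMD ranking
#'
#' @param ranking An `mrmd_ranking`.
#' @param k Number of features.
#' @return Character vector of the k top-ranked feature names.
#' @export
mrmd_top <- function(ranking, k) {
  ranking$feature[order(ranking$rank)][seq_len(k)]
}

#' Export an MRMD ranking as TSV
#'
#' @param ranking An `mrmd_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrmd <- function(ranking, path) {
  out <- ranking[order(ranking$rank),
                 c("feature", "relevance", "distance", "score", "rank")]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

default_knn_factory <- function(k = 5L) {
  function(x_train, y_train) {
    force(x_train); force(y_train)
    function(x_test) knn_predict(x_train, y_train, x_test, k = k)$class
  }
}

#' Sweep the number of top-ranked features by cross-validated accuracy
#'
#' For each `k` in the grid, evaluates CV accuracy with the top-k MRMD
#' features and returns the `k` maximizing mean accuracy (ties broken
#' toward the smallest k) together with the boolean feature mask.
#'
#' @param table A [feature_table()].
#' @param ranking An `mrmd_ranking` of the same features.
#' @param classifier_factory `function(x_train, y_train)` returning a
#'   `function(x_test)` that predicts class labels; default is a
#'   5-nearest-neighbour classifier.
#' @param k_grid Integer feature counts to try; default: every multiple
#'   of 5 from 5 to the feature count (plus the feature count itself).
#' @param n_folds,seed Cross-validation plan.
#' @return List with `best_k`, `mask` (named logical over features) and
#'   `results` (k, mean CV accuracy).
#' @export
sweep_select <- function(table, ranking, classifier_factory = NULL,
                         k_grid = NULL, n_folds = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), inherits(ranking, "mrmd_ranking"))
  p <- ncol(table$x)
  k_grid <- k_grid %||% unique(c(seq(5L, p, by = 5L), p))
  if (length(k_grid) == 0L) stop("empty k_grid", call. = FALSE)
  if (any(k_grid < 1L | k_grid > p)) {
    stop("k_grid values must be in [1, n_features]", call. = FALSE)
  }
  classifier_factory <- classifier_factory %||% default_knn_factory()
  folds <- make_folds(table$labels, n_folds = n_folds, seed = seed)
  ranked <- order(ranking$rank)
  acc <- vapply(k_grid, function(k) {
    keep <- ranked[seq_len(k)]
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- classifier_factory(table$x[tr, keep, drop = FALSE], table$labels[tr])
      pred <- fit(table$x[!tr, keep, drop = FALSE])
      correct <- correct + sum(pred == table$labels[!tr])
    }
    correct / length(table$labels)
  }, numeric(1L))
  ord <- order(k_grid)  # which.max takes the first maximum, so ties go to smallest k
  acc_sorted <- acc[ord]; grid_sorted <- k_grid[ord]
  best <- grid_sorted[which.max(acc_sorted)]
  mask <- stats::setNames(logical(p), table$feature_names)
  mask[ranked[seq_len(best)]] <- TRUE
  list(best_k = best,
       mask = mask,
       results = data.frame(k = grid_sorted, accuracy = acc_sorted))
}
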