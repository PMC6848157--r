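#' Rectified linear unit
#'
#' `f(x) = max(0, x)`, applied elementwise.
#'
#' @param x Numeric vector or matrix.
#' @return Object of the same shape.
#' @export
relu <- function(x) pmax(x, 0)

#' Numerically stable softmax
#'
#' Shift-invariant: `softmax(z) == softmax(z + c)` for any constant `c`,
#' which is exploited (subtracting the maximum) to avoid overflow.
#'
#' @param z Numeric vector with finite entries.
#' @return Probability vector in (0, 1) summing to 1.
#' @export
softmax <- function(z) {
  if (any(!is.finite(z))) stop("softmax requires finite input", call. = FALSE)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Configuration of the 1D convolutional classifier
#'
#' Architecture: input (1 x `input_dim`) -> 1D convolution (`n_filters`
#' filters, kernel `kernel`, stride 1, no padding, linear) -> ReLU ->
#' max-pool (size 2, stride 2) -> dropout (train-time only) -> flatten ->
#' fully connected layer to 2 units -> softmax.  Defaults are the tuned
#' optimum: 64 filters, kernel 3, dropout 0.3, weight max-norm 4, batch
#' size 100, 100 epochs, adadelta.
#'
#' @param input_dim Number of input features.
#' @param n_filters,kernel,pool_size,pool_stride Convolution/pooling
#'   geometry.
#' @param dropout Dropout probability in \[0, 1).
#' @param weight_max_norm Max-norm bound applied to every convolution
#'   filter's kernel vector after each update.
#' @param batch_size,epochs Mini-batch training schedule.
#' @param rho,eps Adadelta decay rate and stabilizer.
#' @param seed Integer seed (initialization, batch order, dropout).
#' @return A `cnn_config`.
#' @export
cnn_config <- function(input_dim, n_filters = 64L, kernel = 3L,
                       pool_size = 2L, pool_stride = 2L, dropout = 0.3,
                       weight_max_norm = 4, batch_size = 100L, epochs = 100L,
                       rho = 0.95, eps = 1e-6, seed = 1L) {
  input_dim <- as.integer(input_dim)
  if (kernel > input_dim) {
    stop(sprintf("kernel (%d) exceeds input_dim (%d)", kernel, input_dim),
         call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  conv_len <- input_dim - as.integer(kernel) + 1L
  pool_len <- (conv_len - as.integer(pool_size)) %/% as.integer(pool_stride) + 1L
  if (pool_len < 1L) {
    stop("input too small: pooled length would be zero", call. = FALSE)
  }
  structure(list(input_dim = input_dim, n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel), pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride), dropout = dropout,
                 weight_max_norm = weight_max_norm,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 rho = rho, eps = eps, output_units = 2L,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Layer shapes implied by a CNN configuration
#'
#' @param config A [cnn_config()] (or an `input_dim` integer, with
#'   default geometry).
#' @return List with `conv_len`, `pool_len`, `flat_dim` and `n_params`.
#' @export
cnn_shapes <- function(config) {
  if (is.numeric(config)) config <- cnn_config(config)
  conv_len <- config$input_dim - config$kernel + 1L
  pool_len <- (conv_len - config$pool_size) %/% config$pool_stride + 1L
  flat_dim <- config$n_filters * pool_len
  n_params <- config$n_filters * config$kernel + config$n_filters +
    flat_dim * config$output_units + config$output_units
  list(conv_len = conv_len, pool_len = pool_len, flat_dim = flat_dim,
       n_params = n_params)
}

glorot_uniform <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

#' Build an untrained 1D CNN
#'
#' Parameters are Glorot-uniform initialized from the configured seed, so
#' the parameter count (and, given a seed, the parameters themselves) is
#' a pure function of the configuration.
#'
#' @param config A [cnn_config()].
#' @return A `cnn_model` (untrained).
#' @export
build_cnn <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  shapes <- cnn_shapes(config)
  params <- with_local_seed(config$seed, {
    list(Wc = glorot_uniform(config$n_filters, config$kernel,
                             fan_in = config$kernel, fan_out = config$n_filters),
         bc = numeric(config$n_filters),
         Wd = glorot_uniform(shapes$flat_dim, config$output_units,
                             fan_in = shapes$flat_dim,
                             fan_out = config$output_units),
         bd = numeric(config$output_units))
  })
  structure(list(config = config, shapes = shapes, params = params,
                 trained = FALSE, history = numeric(),
                 center = NULL, scale = NULL, classes = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %d -> conv %d x %d filters -> pool %d -> dense 2 (%s; %d params)\n",
              x$config$input_dim, x$shapes$conv_len, x$config$n_filters,
              x$shapes$pool_len, if (x$trained) "trained" else "untrained",
              x$shapes$n_params))
  invisible(x)
}

#' Train the 1D CNN on a feature table
#'
#' Mini-batch adadelta training of the softmax cross-entropy loss, with
#' the max-norm constraint re-imposed on every convolution filter after
#' each update.  Features are z-standardized with training statistics
#' (stored on the model and re-applied at prediction time).  Training is
#' single-threaded and fully determined by the configuration seed.
#'
#' @param model A `cnn_model` from [build_cnn()] (or a [cnn_config()]).
#' @param table A [feature_table()] with both classes present.
#' @param standardize Standardize features with training statistics
#'   (default `TRUE`).
#' @return The trained `cnn_model`, with per-epoch loss in `$history`.
#' @export
train_cnn <- function(model, table, standardize = TRUE) {
  if (inherits(model, "cnn_config")) model <- build_cnn(model)
  stopifnot(inherits(model, "cnn_model"), inherits(table, "feature_table"))
  cfg <- model$config
  if (ncol(table$x) != cfg$input_dim) {
    stop(sprintf("feature count (%d) does not match input_dim (%d)",
                 ncol(table$x), cfg$input_dim), call. = FALSE)
  }
  y <- as.integer(table$labels == table$positive)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  x <- table$x
  if (standardize) {
    std <- standardize_columns(x)
    x <- std$x
    model$center <- std$center
    model$scale <- std$scale
  }
  fit <- cnn_train_cpp(x, y, model$params$Wc, model$params$bc,
                       model$params$Wd, model$params$bd,
                       cfg$n_filters, cfg$kernel, cfg$pool_size, cfg$pool_stride,
                       cfg$dropout, cfg$weight_max_norm, cfg$batch_size,
                       cfg$epochs, cfg$rho, cfg$eps, cfg$seed)
  if (!fit$ok) {
    stop(sprintf("training aborted: non-finite loss at epoch %d", fit$epoch),
         call. = FALSE)
  }
  model$params <- list(Wc = fit$Wc, bc = drop(fit$bc),
                       Wd = fit$Wd, bd = drop(fit$bd))
  model$history <- as.numeric(fit$loss)
  model$trained <- TRUE
  model$classes <- c(negative = setdiff(unique(table$labels), table$positive),
                     positive = table$positive)
  model
}

#' Class probabilities from a (trained) CNN
#'
#' Inference is deterministic: dropout is the identity map.  The class
#' call is the argmax, with probability ties going to the positive class.
#'
#' @param object A `cnn_model`.
#' @param table A [feature_table()] (or bare feature matrix) with the
#'   model's `input_dim` columns.
#' @param type `"prob"` for the two-column probability matrix
#'   (negative, positive), `"class"` for label calls.
#' @param ... Unused.
#' @return Matrix of probabilities (rows sum to 1) or character vector
#'   of calls.
#' @export
predict.cnn_model <- function(object, table, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(table, "feature_table")) table$x else as.matrix(table)
  if (ncol(x) != object$config$input_dim) {
    stop(sprintf("feature count (%d) does not match input_dim (%d)",
                 ncol(x), object$config$input_dim), call. = FALSE)
  }
  if (!is.null(object$center)) {
    x <- sweep(sweep(x, 2L, object$center, "-"), 2L, object$scale, "/")
  }
  probs <- cnn_predict_cpp(x, object$params$Wc, object$params$bc,
                           object$params$Wd, object$params$bd,
                           object$config$n_filters, object$config$kernel,
                           object$config$pool_size, object$config$pool_stride)
  colnames(probs) <- if (!is.null(object$classes)) unname(object$classes) else c("negative", "positive")
  if (type == "prob") return(probs)
  pos <- colnames(probs)[2L]
  neg <- colnames(probs)[1L]
  ifelse(probs[, 2L] >= probs[, 1L], pos, neg)
}

#' k-nearest-neighbour prediction
#'
#' Euclidean distances, majority vote over the `k` nearest training
#' points; vote ties go to the positive class.
#'
#' @param x_train,y_train Training features and labels.
#' @param x_test Test features.
#' @param k Number of neighbours (default 10).
#' @param positive Positive class label (default: last sorted label).
#' @return List with `class` (calls) and `score` (fraction of positive
#'   votes, usable as a ranking score).
#' @export
knn_predict <- function(x_train, y_train, x_test, k = 10L, positive = NULL) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(x_train)) stop("k exceeds training-set size", call. = FALSE)
  y_train <- as.character(y_train)
  positive <- positive %||% sort(unique(y_train))[length(unique(y_train))]
  ## squared Euclidean distances via the gram expansion
  d2 <- outer(rowSums(x_test^2), rowSums(x_train^2), "+") -
    2 * tcrossprod(x_test, x_train)
  is_pos <- y_train == positive
  score <- apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    mean(is_pos[nn])
  })
  cls <- ifelse(score >= 0.5, positive, setdiff(unique(y_train), positive)[1L])
  list(class = cls, score = score)
}

#' Cross-validated k-nearest-neighbour baseline
#'
#' Runs kNN under the same stratified cross-validation harness as the
#' CNN and reports the same metrics.
#'
#' @param table A [feature_table()].
#' @param k Number of neighbours (default 10).
#' @param n_folds,seed Fold plan.
#' @param standardize Standardize with training-fold statistics.
#' @return A data frame of per-fold metrics with a `summary` attribute
#'   (means and sds).
#' @export
knn_baseline <- function(table, k = 10L, n_folds = 5L, seed = 1L,
                         standardize = TRUE) {
  cv_table(table,
           fit = function(tr) tr,
           predict_scores = function(tr, te) {
             xtr <- tr$x; xte <- te$x
             if (standardize) {
               std <- standardize_columns(xtr)
               xtr <- std$x
               xte <- sweep(sweep(xte, 2L, std$center, "-"), 2L, std$scale, "/")
             }
             knn_predict(xtr, tr$labels, xte, k = k, positive = tr$positive)$score
           },
           n_folds = n_folds, seed = seed)
}
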