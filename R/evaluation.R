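#' Cross-validation fold assignments
#'
#' Five folds by default, giving the fixed 4:1 training:validation ratio
#' with alternation.  Stratified by default: each class's members are
#' dealt round-robin across folds after a seeded shuffle, so per-fold
#' class proportions match the dataset within one sample.
#'
#' @param labels Class labels (or a `prom_dataset`, whose labels are
#'   used).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed; the same seed reproduces the assignments.
#' @param stratified Stratify by class (default `TRUE`).
#' @return Integer vector of fold indices in 1..`n_folds`, class
#'   `fold_plan`.
#' @export
make_folds <- function(labels, n_folds = 5L, seed = 1L, stratified = TRUE) {
  if (inherits(labels, "prom_dataset")) labels <- labels$label
  labels <- as.character(labels)
  n <- length(labels)
  n_folds <- as.integer(n_folds)
  assignments <- integer(n)
  with_local_seed(as.integer(seed), {
    if (stratified) {
      fold_totals <- integer(n_folds)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < n_folds) {
          stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                       cl, length(idx), n_folds), call. = FALSE)
        }
        idx <- idx[sample.int(length(idx))]
        base <- length(idx) %/% n_folds
        extra <- length(idx) %% n_folds
        ## remainder goes to the currently smallest folds so overall fold
        ## sizes stay within one sample of each other across classes
        sizes <- rep.int(base, n_folds)
        if (extra > 0L) {
          sizes[order(fold_totals, seq_len(n_folds))[seq_len(extra)]] <-
            base + 1L
        }
        assignments[idx] <- rep.int(seq_len(n_folds), sizes)
        fold_totals <- fold_totals + sizes
      }
    } else {
      if (n < n_folds) stop("fewer samples than folds", call. = FALSE)
      assignments[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  structure(assignments, n_folds = n_folds, seed = as.integer(seed),
            stratified = stratified, class = c("fold_plan", "integer"))
}

#' Confusion counts in both standard and Chou notation
#'
#' Chou's symbols relate to the standard counts by N+- = FP, N-+ = FN,
#' N+ = TP + N-+, N- = TN + N+-.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive Positive class label (default: last sorted label of
#'   `y_true`).
#' @return A `confusion_counts` list: `TP`, `TN`, `FP`, `FN`, `Npos`
#'   (N+), `Nneg` (N-), `Npm` (N+-), `Nmp` (N-+).
#' @export
confusion_counts <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  positive <- positive %||% sort(unique(y_true))[length(unique(y_true))]
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 Npos = tp + fn, Nneg = tn + fp, Npm = fp, Nmp = fn,
                 positive = positive),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (positive = '%s')\n",
              x$TP, x$TN, x$FP, x$FN, x$positive))
  invisible(x)
}

#' Sensitivity, specificity, accuracy and MCC in Chou's formulation
#'
#' Computed from the Chou-notation counts:
#' Sens = 1 - N-+/N+, Spec = 1 - N+-/N-,
#' Acc = 1 - (N-+ + N+-)/(N+ + N-), and
#' MCC = (1 - (N-+/N+ + N+-/N-)) /
#' sqrt((1 + (N+- - N-+)/N+) (1 + (N-+ - N+-)/N-)).
#' These are algebraically identical to the familiar TP/TN/FP/FN closed
#' forms.  A zero MCC denominator (a degenerate table) is reported as
#' MCC = 0 with `mcc_undefined = TRUE`.
#'
#' @param counts A [confusion_counts()].
#' @return A `metrics_report` list with `sens`, `spec`, `acc`, `mcc`
#'   (fractions / correlation, unformatted) and the counts.
#' @export
chou_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  Np <- counts$Npos; Nn <- counts$Nneg
  Nmp <- counts$Nmp; Npm <- counts$Npm
  if (Np + Nn == 0L) stop("empty confusion counts", call. = FALSE)
  sens <- if (Np > 0L) 1 - Nmp / Np else NA_real_
  spec <- if (Nn > 0L) 1 - Npm / Nn else NA_real_
  acc <- 1 - (Nmp + Npm) / (Np + Nn)
  mcc_undefined <- FALSE
  den2 <- (1 + (Npm - Nmp) / Np) * (1 + (Nmp - Npm) / Nn)
  if (Np == 0L || Nn == 0L || !is.finite(den2) || den2 <= 0) {
    mcc <- 0
    mcc_undefined <- TRUE
  } else {
    mcc <- (1 - (Nmp / Np + Npm / Nn)) / sqrt(den2)
  }
  structure(list(sens = sens, spec = spec, acc = acc, mcc = mcc,
                 mcc_undefined = mcc_undefined, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2L, ...) {
  cat(sprintf("<metrics_report> Sens %.*f%% Spec %.*f%% Acc %.*f%% MCC %.3f%s\n",
              digits, 100 * x$sens, digits, 100 * x$spec, digits, 100 * x$acc,
              x$mcc, if (!is.null(x$auc)) sprintf(" AUC %.3f", x$auc) else ""))
  invisible(x)
}

## round half away from zero at `digits` decimals (report-time convention)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a metric fraction as percent
#'
#' Metrics are carried as exact fractions internally and rounded
#' half-up only at report time (2 decimals for layer 1, 1 for layer 2 by
#' convention).
#'
#' @param frac Fraction in \[0, 1\].
#' @param digits Decimal places.
#' @return Numeric percentage.
#' @export
percent <- function(frac, digits = 2L) round_half_up(100 * frac, digits)

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney statistic — the probability that a random
#' positive outranks a random negative, ties counted half — computed
#' from score ranks; the returned ROC points (ties grouped per distinct
#' score) integrate to the same value by the trapezoid rule.
#'
#' @param y_true Labels; both classes must be present.
#' @param scores Numeric scores, larger = more positive.
#' @param positive Positive class label.
#' @return List with `auc` and `roc` (data frame of `threshold`, `fpr`,
#'   `tpr` including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(y_true, scores, positive = NULL) {
  y_true <- as.character(y_true)
  positive <- positive %||% sort(unique(y_true))[length(unique(y_true))]
  pos <- y_true == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present for ROC/AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # group tied scores
  tpr <- c(0, cumsum(p)[keep] / n_pos)
  fpr <- c(0, cumsum(!p)[keep] / n_neg)
  roc <- data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr)
  list(auc = auc, roc = roc)
}

#' Generic repeated cross-validation over a feature table
#'
#' @param table A [feature_table()].
#' @param fit `function(train_table)` returning a fitted object.
#' @param predict_scores `function(fitted, test_table)` returning
#'   positive-class scores for the test rows.
#' @param n_folds,n_repeats Plan size.
#' @param seed Base seed; repeat r uses `seed + 7919 * (r - 1)`.
#' @param threshold Score threshold for the class call (default 0.5,
#'   ties to positive).
#' @return Data frame of per-repeat per-fold metrics (`sens`, `spec`,
#'   `acc`, `mcc`, `auc`) with a `summary` attribute of means and sds.
#' @export
cv_table <- function(table, fit, predict_scores, n_folds = 5L, n_repeats = 1L,
                     seed = 1L, threshold = 0.5) {
  rows <- list()
  for (r in seq_len(n_repeats)) {
    folds <- make_folds(table$labels, n_folds = n_folds,
                        seed = seed + 7919L * (r - 1L))
    for (f in seq_len(n_folds)) {
      tr <- subset_table(table, rows = which(folds != f))
      te <- subset_table(table, rows = which(folds == f))
      fitted <- fit(tr)
      score <- predict_scores(fitted, te)
      rows[[length(rows) + 1L]] <- fold_metrics(te$labels, score, te$positive,
                                                repeat_id = r, fold_id = f,
                                                threshold = threshold)
    }
  }
  finish_cv(rows)
}

fold_metrics <- function(y_true, score, positive, repeat_id, fold_id,
                         threshold = 0.5) {
  negative <- setdiff(unique(y_true), positive)[1L]
  call <- ifelse(score >= threshold, positive, negative)
  m <- chou_metrics(confusion_counts(y_true, call, positive = positive))
  auc <- roc_auc(y_true, score, positive = positive)$auc
  data.frame(repeat_id = repeat_id, fold_id = fold_id,
             sens = m$sens, spec = m$spec, acc = m$acc, mcc = m$mcc, auc = auc)
}

finish_cv <- function(rows) {
  res <- do.call(rbind, rows)
  metrics <- c("sens", "spec", "acc", "mcc", "auc")
  summary <- data.frame(metric = metrics,
                        mean = vapply(metrics, function(m) mean(res[[m]]), numeric(1L)),
                        sd = vapply(metrics, function(m) stats::sd(res[[m]]), numeric(1L)))
  rownames(summary) <- NULL
  attr(res, "summary") <- summary
  res
}

#' Mean of a cross-validation metric
#'
#' @param cv_results Result of [cv_table()], [knn_baseline()] or
#'   [promoter_cv()].
#' @param metric One of `"sens"`, `"spec"`, `"acc"`, `"mcc"`, `"auc"`.
#' @return Numeric mean over repeats and folds.
#' @export
cv_mean <- function(cv_results, metric = "auc") {
  mean(cv_results[[metric]])
}

#' One-sided Wilcoxon signed-rank test (paired, "a greater than b")
#'
#' Zero differences are dropped; |differences| are ranked with average
#' ties.  For n <= 25 pairs the p-value is exact — the full null
#' distribution of the positive-rank sum over all 2^n sign assignments,
#' computed by generating-function convolution; above that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Paired numeric vectors of equal length (>= 5 after
#'   dropping zero differences).
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`
#'   and `n` (pairs used).
#' @export
wilcoxon_one_sided <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; test undefined", call. = FALSE)
  if (n < 5L) warning("fewer than 5 nonzero differences; test has little power")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    ir <- as.integer(round(2 * r))      # doubled ranks are integers even with ties
    total <- sum(ir)
    counts <- numeric(total + 1L)       # counts[s + 1] = #subsets with doubled sum s
    counts[1L] <- 1
    for (v in ir) {
      shifted <- c(numeric(v), counts[seq_len(total + 1L - v)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * W))
    p <- sum(counts[seq.int(w2 + 1L, total + 1L)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(statistic = W, p_value = p, n = n)
}
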