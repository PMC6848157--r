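test_that("fold plans partition samples with the 4:1 ratio and stratification", {
  y10 <- rep(c("a", "b"), 5)
  f <- make_folds(y10, 5, seed = 1)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_identical(as.integer(f), as.integer(make_folds(y10, 5, seed = 1)))

  set.seed(2)
  y <- sample(rep(c("x", "y"), c(130, 70)))
  f <- make_folds(y, 5, seed = 9)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 200L)               # every sample in exactly one fold
  per_fold <- table(f, y)
  expect_true(all(abs(per_fold[, "x"] - 26) <= 1))
  expect_true(all(abs(per_fold[, "y"] - 14) <= 1))

  # 6,764 samples split 5 ways -> validation folds of 1,352-1,353
  big <- make_folds(rep(c("p", "n"), 3382), 5, seed = 3)
  expect_true(all(table(big) %in% c(1352L, 1353L)))

  expect_error(make_folds(c("a", "a", "b"), 5), "fewer members")
})

test_that("confusion counts follow their definition and Chou identities", {
  all_right <- confusion_counts(rep(c("p", "n"), each = 5),
                                rep(c("p", "n"), each = 5), positive = "p")
  expect_equal(unlist(all_right[c("TP", "TN", "FP", "FN")]),
               c(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  all_wrong <- confusion_counts(rep(c("p", "n"), each = 5),
                                rep(c("n", "p"), each = 5), positive = "p")
  expect_equal(all_wrong$TP + all_wrong$TN, 0L)

  set.seed(7)
  y <- sample(c("p", "n"), 200, replace = TRUE)
  pred <- sample(c("p", "n"), 200, replace = TRUE)
  cc <- confusion_counts(y, pred, positive = "p")
  tally <- c(TP = sum(y == "p" & pred == "p"), TN = sum(y == "n" & pred == "n"),
             FP = sum(y == "n" & pred == "p"), FN = sum(y == "p" & pred == "n"))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), tally)
  expect_equal(cc$Npm, cc$FP)                # N+- = FP
  expect_equal(cc$Nmp, cc$FN)                # N-+ = FN
  expect_equal(cc$Npos, cc$TP + cc$FN)
  expect_equal(cc$Nneg, cc$TN + cc$FP)

  expect_error(confusion_counts(c("p", "n"), "p"), "equal length")
})

test_that("Chou-form metrics equal the standard closed forms", {
  set.seed(15)
  for (i in 1:300) {
    counts <- sample(0:40, 4, replace = TRUE)
    if (counts[1] + counts[4] == 0 || counts[2] + counts[3] == 0) next
    cc <- structure(list(TP = counts[1], TN = counts[2], FP = counts[3],
                         FN = counts[4], Npos = counts[1] + counts[4],
                         Nneg = counts[2] + counts[3], Npm = counts[3],
                         Nmp = counts[4], positive = "p"),
                    class = "confusion_counts")
    m <- chou_metrics(cc)
    TP <- counts[1]; TN <- counts[2]; FP <- counts[3]; FN <- counts[4]
    expect_equal(m$sens, TP / (TP + FN))
    expect_equal(m$spec, TN / (TN + FP))
    expect_equal(m$acc, (TP + TN) / sum(counts))
    mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
    if (mcc_den > 0) {
      expect_equal(m$mcc, (TP * TN - FP * FN) / mcc_den, tolerance = 1e-12)
      expect_true(m$mcc >= -1 && m$mcc <= 1)
    } else {
      expect_true(m$mcc_undefined)
      expect_equal(m$mcc, 0)
    }
  }
})

test_that("balanced designs force Acc = (Sens + Spec) / 2 and perfection is 1", {
  cc <- confusion_counts(rep(c("p", "n"), each = 50),
                         c(rep("p", 40), rep("n", 10), rep("n", 45), rep("p", 5)),
                         positive = "p")
  m <- chou_metrics(cc)
  expect_equal(m$acc, (m$sens + m$spec) / 2)

  perfect <- chou_metrics(confusion_counts(c("p", "p", "n"), c("p", "p", "n"),
                                           positive = "p"))
  expect_equal(unlist(perfect[c("sens", "spec", "acc", "mcc")]),
               c(sens = 1, spec = 1, acc = 1, mcc = 1))
})

test_that("AUC equals the pairwise Mann-Whitney probability", {
  y <- rep(c("n", "p"), each = 5)
  expect_equal(roc_auc(y, c(1:5, 6:10), positive = "p")$auc, 1.0)
  expect_equal(roc_auc(y, c(6:10, 1:5), positive = "p")$auc, 0.0)
  expect_error(roc_auc(rep("p", 4), rnorm(4)), "both classes")

  set.seed(18)
  for (i in 1:20) {
    y <- sample(c("n", "p"), 30, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # ties guaranteed
    r <- roc_auc(y, s, positive = "p")
    expect_equal(r$auc, auc_pairwise(y, s, "p"), tolerance = 1e-12)
    trapz <- sum(diff(r$roc$fpr) * (head(r$roc$tpr, -1) + tail(r$roc$tpr, -1)) / 2)
    expect_equal(trapz, r$auc, tolerance = 1e-12)
  }
})

test_that("AUC is antisymmetric under score negation without ties", {
  set.seed(19)
  y <- rep(c("n", "p"), 15)
  s <- rnorm(30)
  expect_equal(roc_auc(y, s, positive = "p")$auc +
                 roc_auc(y, -s, positive = "p")$auc, 1.0)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  y <- rep(c("n", "p"), each = 25)
  s <- rnorm(50) + (y == "p")
  ours <- roc_auc(y, s, positive = "p")$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                           levels = c("n", "p"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("one-sided Wilcoxon matches exhaustive sign enumeration", {
  # all-positive differences at n = 10 give the extreme p = 1/1024
  w <- wilcoxon_one_sided(2:11, 1:10)
  expect_equal(w$p_value, 1 / 1024)
  expect_equal(w$statistic, 55)

  expect_error(wilcoxon_one_sided(1:5, 1:5), "all differences are zero")

  set.seed(22)
  for (i in 1:5) {
    n <- sample(8:12, 1)
    a <- round(rnorm(n), 1)
    b <- round(rnorm(n), 1)
    if (all(a == b)) next
    expect_equal(wilcoxon_one_sided(a, b)$p_value, wilcoxon_enum(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the exact Wilcoxon branch matches stats::wilcox.test without ties", {
  set.seed(25)
  a <- rnorm(15)
  b <- rnorm(15)
  ours <- wilcoxon_one_sided(a, b)$p_value
  ref <- wilcox.test(a, b, paired = TRUE, alternative = "greater",
                     exact = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("cross-validation bookkeeping is deterministic and complete", {
  tab <- toy_table(n = 40, p = 6, seed = 12)
  stub_fit <- function(tr) tr
  stub_score <- function(fitted, te) rowSums(te$x)     # deterministic stub
  res <- cv_table(tab, stub_fit, stub_score, n_folds = 5, n_repeats = 2,
                  seed = 31)
  expect_equal(nrow(res), 10L)
  expect_equal(sort(unique(res$repeat_id)), 1:2)
  res2 <- cv_table(tab, stub_fit, stub_score, n_folds = 5, n_repeats = 2,
                   seed = 31)
  expect_identical(res, res2)
  s <- attr(res, "summary")
  expect_setequal(s$metric, c("sens", "spec", "acc", "mcc", "auc"))
  expect_equal(cv_mean(res, "auc"), mean(res$auc))
})

test_that("percent formatting rounds half up at report time", {
  expect_equal(percent(0.854065, 2), 85.41)
  expect_equal(percent(0.731008, 1), 73.1)
  expect_equal(percent(0.005, 0), 1)    # half away from zero, not to even
})
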