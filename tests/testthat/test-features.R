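test_that("combining levels concatenates blocks in ascending order", {
  per <- lapply(setNames(1:10, 1:10), function(n) rep(n, 100))
  v <- combine_features(per)
  expect_length(v, 1000L)
  expect_equal(names(v)[1], "feature_1")
  expect_equal(unname(v[1]), 1)
  expect_equal(unname(v[1000]), 10)

  one <- combine_features(list(`3` = rnorm(100)))
  expect_length(one, 100L)
  expect_equal(nrow(attr(one, "layout")), 1L)
})

test_that("slice after combine is the identity on every block", {
  set.seed(2)
  per <- lapply(setNames(1:10, 1:10), function(n) rnorm(20))
  v <- combine_features(per)
  for (n in 1:10) expect_equal(slice_level(v, n), per[[as.character(n)]])

  mats <- lapply(setNames(c(2, 7), c(2, 7)), function(n) matrix(rnorm(30), 5))
  m <- combine_features(mats)
  expect_equal(slice_level(m, 7), unname(mats[["7"]]))
})

test_that("combine validates levels and dimensions", {
  per <- lapply(setNames(1:9, 1:9), function(n) rnorm(10))
  expect_error(combine_features(per, levels = 1:10), "missing levels: 10")
  bad <- list(`1` = rnorm(10), `2` = rnorm(11))
  expect_error(combine_features(bad), "dimension mismatch")
})

test_that("MRMD ranking matches an independent brute-force implementation", {
  set.seed(17)
  for (rep in 1:3) {
    x <- matrix(rnorm(20 * 5), 20, 5)
    y <- rep(c("n", "p"), 10)
    tab <- feature_table(x, y, positive = "p")
    r <- mrmd_rank(tab)
    expect_equal(r$score, mrmd_oracle(x, as.integer(y == "p")),
                 tolerance = 1e-12)
    expect_equal(max(r$score), 1.0)          # top score exactly 1 after normalization
    expect_equal(sort(r$rank), 1:5)
  }
})

test_that("MRMD relevance behaves at the extremes", {
  y <- rep(c(0, 1), 15)
  x <- cbind(lab = y, const = rep(2, 30), noise = rnorm(30))
  tab <- feature_table(x, ifelse(y == 1, "p", "n"), positive = "p")
  r <- mrmd_rank(tab)
  expect_equal(r$relevance[1], 1.0)          # feature identical to the label
  expect_equal(r$relevance[2], 0.0)          # constant feature
  expect_equal(r$rank[1], 1L)
})

test_that("MRMD is invariant to sample order and per-feature rescaling", {
  set.seed(23)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c("n", "p"), 20)
  tab <- feature_table(x, y, positive = "p")
  base <- mrmd_rank(tab)

  perm <- sample(40)
  shuffled <- feature_table(x[perm, ], y[perm], positive = "p")
  expect_equal(mrmd_rank(shuffled)$score, base$score, tolerance = 1e-12)

  rescaled_x <- x
  rescaled_x[, 4] <- x[, 4] * 1000
  rescaled <- feature_table(rescaled_x, y, positive = "p")
  expect_equal(mrmd_rank(rescaled)$score, base$score, tolerance = 1e-12)
})

test_that("MRMD rejects degenerate tables", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(mrmd_rank(feature_table(x, rep("p", 10))), "both classes")
  one_col <- feature_table(matrix(rnorm(10), 10, 1), rep(c("n", "p"), 5),
                           positive = "p")
  expect_error(mrmd_rank(one_col), "2 features")
})

test_that("ranking export lists features in rank order", {
  tab <- toy_table(n = 30, p = 5, seed = 4)
  r <- mrmd_rank(tab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mrmd(r, path)
  back <- read.delim(path)
  expect_equal(back$rank, 1:5)
  expect_equal(back$score[1], 1.0)
  expect_setequal(back$feature, tab$feature_names)
})

test_that("sweep_select recovers a planted informative feature", {
  set.seed(5)
  n <- 60
  y <- rep(c("n", "p"), n / 2)
  x <- matrix(rnorm(n * 50), n, 50)
  x[, 7] <- x[, 7] + 3 * (y == "p")          # one informative among 49 noise
  tab <- feature_table(x, y, positive = "p")
  ranking <- mrmd_rank(tab)
  sel <- sweep_select(tab, ranking, k_grid = c(1, 5, 10, 25, 50), seed = 2)
  expect_true(sel$mask[["feature_7"]])
  expect_lte(sel$best_k, 10L)
  expect_gt(max(sel$results$accuracy), 0.9)
})

test_that("sweep_select edge grids behave as forced", {
  tab <- toy_table(n = 30, p = 6, seed = 8)
  ranking <- mrmd_rank(tab)
  all_k <- sweep_select(tab, ranking, k_grid = 6L, seed = 1)
  expect_true(all(all_k$mask))
  expect_error(sweep_select(tab, ranking, k_grid = integer()), "empty k_grid")
  expect_error(sweep_select(tab, ranking, k_grid = c(1, 99)), "n_features")

  # label duplicate + pure noise: k = 1 beats using everything
  set.seed(9)
  y <- rep(c("n", "p"), 25)
  x <- cbind(2 * (y == "p"), matrix(rnorm(50 * 49), 50, 49))
  dup <- feature_table(x, y, positive = "p")
  sel <- sweep_select(dup, mrmd_rank(dup), k_grid = c(1L, 50L), seed = 3)
  expect_equal(sel$best_k, 1L)
})
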