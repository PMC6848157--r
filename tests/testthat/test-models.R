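test_that("relu and softmax satisfy their defining identities", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(2), 2)
  expect_equal(relu(c(-1, 0, 5)), c(0, 0, 5))

  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(1000, 1000)), c(0.5, 0.5))   # no overflow
  z <- c(1, 2, 3)
  expect_equal(softmax(z), exp(z) / sum(exp(z)), tolerance = 1e-15)
  expect_error(softmax(c(1, Inf)), "finite")
  expect_error(softmax(c(1, NA)), "finite")
})

test_that("softmax is shift-invariant and normalized on random draws", {
  set.seed(4)
  for (i in 1:200) {
    z <- rnorm(sample(2:8, 1), sd = 10)
    p <- softmax(z)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
    expect_equal(softmax(z + 17.3), p, tolerance = 1e-12)
  }
})

test_that("layer shape arithmetic matches the closed form", {
  s1000 <- cnn_shapes(cnn_config(1000))
  expect_equal(s1000$conv_len, 998L)
  expect_equal(s1000$pool_len, 499L)
  expect_equal(s1000$flat_dim, 31936L)
  s100 <- cnn_shapes(cnn_config(100))
  expect_equal(unlist(s100[c("conv_len", "pool_len", "flat_dim")]),
               c(conv_len = 98L, pool_len = 49L, flat_dim = 3136L))

  for (d in c(4, 5, 17, 100, 333, 999, 2000)) {
    sh <- cnn_shapes(cnn_config(d))
    conv <- d - 3 + 1
    expect_equal(sh$conv_len, conv)
    expect_equal(sh$pool_len, (conv - 2) %/% 2 + 1)
    expect_equal(sh$flat_dim, 64 * sh$pool_len)
    expect_equal(sh$n_params, 64 * 3 + 64 + sh$flat_dim * 2 + 2)
  }
  expect_error(cnn_config(2), "kernel")
  expect_error(cnn_config(3), "pooled length")
})

test_that("a frozen one-filter network reproduces hand propagation", {
  cfg <- cnn_config(6, n_filters = 1L, epochs = 1L, dropout = 0)
  model <- build_cnn(cfg)
  model$params$Wc <- matrix(c(1, 0, -1), 1, 3)
  model$params$bc <- 0.25
  model$params$Wd <- matrix(c(0.5, -1, 1.5, 2), 2, 2)   # flat_dim = 2
  model$params$bd <- c(0.1, -0.2)
  x <- matrix(c(0.3, -1.2, 2.0, 0.7, -0.5, 1.1), 1, 6)

  conv <- sapply(1:4, function(p) sum(x[1, p:(p + 2)] * c(1, 0, -1)) + 0.25)
  act <- pmax(conv, 0)
  pooled <- c(max(act[1:2]), max(act[3:4]))
  logits <- as.numeric(pooled %*% model$params$Wd) + model$params$bd
  expect_equal(unname(predict(model, x)[1, ]), softmax(logits),
               tolerance = 1e-12)
})

test_that("prediction is a deterministic probability distribution", {
  tab <- toy_table(n = 24, p = 6, seed = 7)
  net <- train_cnn(build_cnn(cnn_config(6, epochs = 10, batch_size = 8, seed = 2)),
                   tab)
  p <- predict(net, tab)
  expect_equal(rowSums(p), rep(1, 24), tolerance = 1e-9)
  dup <- rbind(tab$x[1, , drop = FALSE], tab$x[1, , drop = FALSE])
  pd <- predict(net, dup)
  expect_identical(pd[1, ], pd[2, ])          # dropout is identity at inference
  expect_error(predict(net, tab$x[, 1:4]), "input_dim")
})

test_that("training separates a linearly separable toy set and respects max-norm", {
  set.seed(6)
  n <- 60
  y <- rep(c("neg", "pos"), n / 2)
  x <- matrix(rnorm(n * 4, sd = 0.3), n, 4)
  x[, 1] <- x[, 1] + ifelse(y == "pos", 2, -2)
  tab <- feature_table(x, y, positive = "pos")
  net <- train_cnn(build_cnn(cnn_config(4, epochs = 100, batch_size = 20, seed = 3)),
                   tab)
  expect_equal(unname(predict(net, tab, type = "class")), y)
  filter_norms <- sqrt(rowSums(net$params$Wc^2))
  expect_true(all(filter_norms <= net$config$weight_max_norm + 1e-6))
  expect_length(net$history, 100L)
  expect_lt(tail(net$history, 1), net$history[1])

  # reproducibility under the single-threaded seeded contract
  net2 <- train_cnn(build_cnn(cnn_config(4, epochs = 100, batch_size = 20, seed = 3)),
                    tab)
  expect_identical(net$params, net2$params)
})

test_that("train_cnn rejects single-class and mismatched input", {
  tab <- toy_table(n = 20, p = 6)
  one_class <- feature_table(tab$x, rep("pos", 20), positive = "pos")
  expect_error(train_cnn(build_cnn(cnn_config(6, epochs = 1)), one_class),
               "both classes")
  expect_error(train_cnn(build_cnn(cnn_config(8, epochs = 1)), tab),
               "input_dim")
})

test_that("kNN prediction votes among Euclidean neighbours with positive ties", {
  xtr <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), 4, 2, byrow = TRUE)
  ytr <- c("neg", "neg", "pos", "pos")
  # k = 1: a training point queried against itself returns its own label
  self <- knn_predict(xtr, ytr, xtr, k = 1, positive = "pos")
  expect_equal(self$class, ytr)
  # k = n: majority class everywhere (here a 2-2 tie -> positive)
  all_of_them <- knn_predict(xtr, ytr, matrix(c(5, 5), 1, 2), k = 4,
                             positive = "pos")
  expect_equal(all_of_them$class, "pos")
  expect_error(knn_predict(xtr, ytr, xtr, k = 0), "k must be")
  expect_error(knn_predict(xtr, ytr, xtr, k = 9), "exceeds")
})

test_that("kNN separates two well-separated Gaussian blobs", {
  set.seed(10)
  n <- 100
  y <- rep(c("neg", "pos"), n / 2)
  x <- matrix(rnorm(n * 5), n, 5) + ifelse(y == "pos", 4, 0)
  res <- knn_baseline(feature_table(x, y, positive = "pos"), k = 10, seed = 4)
  expect_gte(mean(res$acc), 0.95)
  expect_equal(nrow(res), 5L)
})
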