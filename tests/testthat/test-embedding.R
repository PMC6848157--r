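test_that("char_ngrams reproduces the subword worked example", {
  expect_setequal(char_ngrams("ATGAC", 3, 3),
                  c("<AT", "ATG", "TGA", "GAC", "AC>", "<ATGAC>"))
  expect_equal(char_ngrams("A", 3, 3), "<A>")
  # the whole-word token of a short word differs from an equal-looking
  # interior gram of a longer word
  expect_true("<TGA>" %in% char_ngrams("TGA", 3, 3))
  expect_true("TGA" %in% char_ngrams("ATGAC", 3, 3))
  expect_error(char_ngrams("ACGT", 4, 3), "minn")
  expect_error(char_ngrams(""), "non-empty")
})

test_that("char_ngrams agrees with exhaustive enumeration and its size law", {
  set.seed(8)
  for (i in 1:40) {
    len <- sample(1:10, 1)
    w <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    minn <- sample(1:6, 1)
    maxn <- (minn:6)[sample.int(7 - minn, 1)]
    got <- char_ngrams(w, minn, maxn)
    expect_setequal(got, char_ngrams_oracle(w, minn, maxn))
    expect_equal(sum(got == paste0("<", w, ">")), 1L)  # exactly one whole-word token
    # single-size closed form: position count + whole-word token.  As a
    # set it holds exactly when all enumerated grams are distinct (a
    # repeat-free word, and n small enough that no interior gram equals
    # the whole-word token).
    n <- sample(1:6, 1)
    wrapped <- paste0("<", w, ">")
    npos <- max(nchar(wrapped) - n + 1, 0)
    enum <- if (npos > 0) substring(wrapped, 1:npos, 1:npos + n - 1) else character()
    if (!anyDuplicated(c(enum, wrapped))) {
      expect_length(char_ngrams(w, n, n), npos + 1)
    }
  }
})

toy_sentences <- list(c("ATG", "TGA", "GAC"), c("TTT", "TTA", "TAC"),
                      c("ATG", "TGC", "GCA"), c("TAC", "ACG", "CGT"))
toy_labels <- c("pos", "neg", "pos", "neg")

test_that("supervised training covers the corpus and is seed-deterministic", {
  cfg <- embedding_config(dim = 8, epoch = 5, seed = 4)
  m <- train_embedding(toy_sentences, toy_labels, cfg)
  corpus_grams <- unique(unlist(lapply(unique(unlist(toy_sentences)),
                                       char_ngrams, minn = 3, maxn = 6)))
  expect_setequal(m$grams, corpus_grams)
  expect_equal(dim(m$input), c(length(m$grams), 8L))
  expect_true(all(is.finite(m$input)))

  m2 <- train_embedding(toy_sentences, toy_labels, cfg)
  expect_identical(m$input, m2$input)
  expect_identical(m$output, m2$output)
  m3 <- train_embedding(toy_sentences, toy_labels,
                        embedding_config(dim = 8, epoch = 5, seed = 5))
  expect_false(identical(m$input, m3$input))
})

test_that("training rejects degenerate inputs", {
  expect_error(train_embedding(list(), NULL, embedding_config()), "empty corpus")
  expect_error(train_embedding(toy_sentences, NULL, embedding_config()),
               "labels")
  expect_error(train_embedding(toy_sentences, rep("pos", 4), embedding_config()),
               "both classes")
  expect_error(train_embedding(toy_sentences, toy_labels,
                               embedding_config(objective = "skipgram",
                                                loss = "hs")),
               "hierarchical")
})

test_that("training loss decreases over epochs on a fixed toy corpus", {
  set.seed(31)
  sents <- lapply(1:30, function(i) {
    tokenize(paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""), 3)
  })
  labs <- rep(c("a", "b"), 15)
  m <- train_embedding(sents, labs, embedding_config(dim = 10, epoch = 60, seed = 2))
  checkpoints <- m$loss_history[c(1, 15, 30, 45, 60)]
  expect_true(all(diff(checkpoints) <= 1e-6))
  expect_lt(checkpoints[5], checkpoints[1])
})

test_that("word-context scores follow the subword dot-product sum", {
  m <- train_embedding(toy_sentences, toy_labels,
                       embedding_config(dim = 6, epoch = 3, seed = 9))
  # all-zero input vectors score zero
  m0 <- m
  m0$input[] <- 0
  expect_equal(embedding_score("ATG", "pos", m0), 0)

  # hand-set identity: one gram, unit basis vectors
  m1 <- m
  m1$input[] <- 0
  m1$output[] <- 0
  gid <- match("<ATG>", m1$grams)
  ci <- match("pos", m1$context_labels)
  m1$input[gid, 1] <- 1
  m1$output[ci, 1] <- 1
  # G_w of "ATG" = {<AT, ATG, TG>, <ATG>}; only <ATG> carries mass
  expect_equal(embedding_score("ATG", "pos", m1), 1.0)

  # random vectors against an explicit double loop
  set.seed(3)
  m$input[] <- rnorm(length(m$input))
  m$output[] <- rnorm(length(m$output))
  gids <- match(char_ngrams("TGA", 3, 6), m$grams)
  gids <- gids[!is.na(gids)]
  manual <- 0
  for (g in gids) manual <- manual + sum(m$input[g, ] * m$output[ci <- match("neg", m$context_labels), ])
  expect_equal(embedding_score("TGA", "neg", m), manual)
  expect_error(embedding_score("TGA", "nonexistent", m), "unknown context")
})

test_that("sequence vectors average word representations", {
  m <- train_embedding(toy_sentences, toy_labels,
                       embedding_config(dim = 5, epoch = 2, seed = 1))
  # one word whose grams all share vector v -> the sequence vector is v
  mv <- m
  v <- c(1, -2, 0.5, 3, -1)
  mv$input <- matrix(rep(v, each = nrow(mv$input)), nrow(mv$input), 5)
  expect_equal(sequence_vector("ATG", mv), v)

  # two words -> midpoint of their representations
  set.seed(12)
  m$input[] <- rnorm(length(m$input))
  rep_of <- function(w) {
    gids <- match(char_ngrams(w, 3, 6), m$grams)
    colMeans(m$input[gids[!is.na(gids)], , drop = FALSE])
  }
  expect_equal(sequence_vector(c("ATG", "TAC"), m),
               (rep_of("ATG") + rep_of("TAC")) / 2)

  # long sentence against a brute-force double loop
  set.seed(14)
  sent <- tokenize(paste(sample(c("A", "C", "G", "T"), 81, TRUE), collapse = ""), 5)
  m5 <- train_embedding(list(sent), NULL,
                        embedding_config(dim = 7, epoch = 1,
                                         objective = "skipgram", loss = "ns",
                                         seed = 2))
  manual <- rowMeans(vapply(sent, function(w) {
    gids <- match(char_ngrams(w, 3, 6), m5$grams)
    colMeans(m5$input[gids[!is.na(gids)], , drop = FALSE])
  }, numeric(7)))
  expect_equal(sequence_vector(sent, m5), manual)

  # mean aggregation is order-invariant in the word multiset
  expect_equal(sequence_vector(sent, m5), sequence_vector(rev(sent), m5))
  expect_equal(unname(sequence_vectors(list(a = sent), m5)[1, ]),
               sequence_vector(sent, m5))

  # a sentence with no known grams yields a zero vector and a warning
  m_small <- train_embedding(list(c("AAA", "AAT")), NULL,
                             embedding_config(dim = 4, epoch = 1, minn = 3,
                                              maxn = 3,
                                              objective = "skipgram",
                                              loss = "ns", seed = 1))
  expect_warning(zv <- sequence_vector("GGGGGGGG", m_small), "zero vector")
  expect_equal(zv, numeric(4))
})

test_that("unsupervised objectives train deterministically and cover the vocab", {
  set.seed(44)
  sents <- lapply(1:10, function(i) {
    tokenize(paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), 4)
  })
  for (obj in c("skipgram", "cbow")) {
    cfg <- embedding_config(dim = 6, epoch = 3, objective = obj, loss = "ns",
                            seed = 11)
    m <- train_embedding(sents, NULL, cfg)
    expect_equal(nrow(m$output), length(m$words))
    expect_true(all(is.finite(m$input)))
    expect_identical(m$input, train_embedding(sents, NULL, cfg)$input)
  }
})

test_that("embedding models persist to text and reload intact", {
  m <- train_embedding(toy_sentences, toy_labels,
                       embedding_config(dim = 6, epoch = 4, seed = 13), level = 3)
  stem <- withr::local_tempfile()
  save_embedding(m, stem)
  back <- load_embedding(stem)
  expect_equal(back$input, m$input, tolerance = 1e-15)
  expect_equal(back$grams, m$grams)
  expect_equal(back$classes, m$classes)
  expect_equal(back$level, 3)
  sent <- toy_sentences[[1]]
  expect_equal(sequence_vector(sent, back), sequence_vector(sent, m),
               tolerance = 1e-15)
})
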