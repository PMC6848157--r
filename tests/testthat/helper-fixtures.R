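# Shared fixture builders; everything is generated in code at test time.

write_fasta_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tiny_dataset <- function(n_pos = 6, n_neg = 6, seed = 1) {
  generate_synthetic(synthetic_spec(n_pos = n_pos, n_neg = n_neg,
                                    seed = seed))$layer1
}

# deterministic toy feature table: first column tracks the label, the
# rest are noise
toy_table <- function(n = 40, p = 8, seed = 3, signal = 2) {
  set.seed(seed)
  y <- rep(c("neg", "pos"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + signal * (y == "pos")
  feature_table(x, y, positive = "pos")
}

# exhaustive pairwise Mann-Whitney AUC (ties counted half)
auc_pairwise <- function(y, s, positive) {
  ps <- s[y == positive]
  ns <- s[y != positive]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# exact one-sided signed-rank p by enumerating all 2^n sign patterns
wilcoxon_enum <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  mean(signs %*% r >= W)
}

# brute-force character n-gram enumeration over the wrapped word
char_ngrams_oracle <- function(word, minn, maxn) {
  wrapped <- paste0("<", word, ">")
  out <- character()
  for (size in minn:maxn) {
    if (size > nchar(wrapped)) next
    for (s in 1:(nchar(wrapped) - size + 1)) {
      out <- c(out, substr(wrapped, s, s + size - 1))
    }
  }
  unique(c(out, wrapped))
}

# independent loop-based MRMD scoring (same formulas, separate code path)
mrmd_oracle <- function(x, y01) {
  z <- scale(x)
  z[is.na(z)] <- 0
  p <- ncol(z)
  mr <- numeric(p)
  for (i in seq_len(p)) {
    if (sd(z[, i]) > 0) mr[i] <- abs(cor(z[, i], y01))
  }
  ed <- cosd <- tand <- numeric(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)[-i]) {
      a <- z[, i]; b <- z[, j]
      ed[i] <- ed[i] + sqrt(sum((a - b)^2))
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      cs <- if (na > 0 && nb > 0) sum(a * b) / (na * nb) else 0
      cosd[i] <- cosd[i] + (1 - cs)
      den <- sum(a^2) + sum(b^2) - sum(a * b)
      ts <- if (den != 0) sum(a * b) / den else 0
      tand[i] <- tand[i] + (1 - ts)
    }
  }
  comp <- cbind(ed, cosd, tand) / (p - 1)
  sc01 <- function(v) if (diff(range(v)) > 0) (v - min(v)) / diff(range(v)) else rep(0, length(v))
  md <- rowMeans(apply(comp, 2, sc01))
  score <- mr + md
  score / max(score)
}
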