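#' Tokenize a DNA sequence into a sentence of k-mer words
#'
#' Level `n` produces all overlapping windows of length `n` at stride 1,
#' left to right on the given strand, so a sequence of length `L` yields
#' `L - n + 1` words.  This is the "k-mer word" reading of an n-gram
#' level; a run may instead realize levels as the subword gram size (see
#' `level_mode` in [promoter_cv()]), but k-mer word length is the default.
#'
#' @param bases A sequence string, or a one-row dataset slice.
#' @param n Word length (n-gram level), integer in 1..10.
#' @param id Record id used in error messages.
#' @return Character vector of words, each of length `n`.
#' @export
tokenize <- function(bases, n, id = NULL) {
  if (is.data.frame(bases)) {
    id <- id %||% bases$id[1L]
    bases <- bases$bases[1L]
  }
  n <- as.integer(n)
  if (n < 1L || n > 10L) stop("n-gram level must be in 1..10", call. = FALSE)
  L <- nchar(bases)
  if (L < n) {
    stop(sprintf("record '%s' (length %d) is shorter than level %d",
                 id %||% "<unnamed>", L, n), call. = FALSE)
  }
  substring(bases, seq_len(L - n + 1L), seq_len(L - n + 1L) + n - 1L)
}

#' Tokenize every record of a dataset at one n-gram level
#'
#' @param dataset A `prom_dataset` (or any data frame with `id` and
#'   `bases` columns).
#' @param n Word length (n-gram level).
#' @return Named list of word vectors, one per record, in dataset order.
#' @export
corpus_sentences <- function(dataset, n) {
  if (nrow(dataset) == 0L) return(stats::setNames(list(), character()))
  out <- lapply(seq_len(nrow(dataset)), function(i) {
    tokenize(dataset$bases[i], n, id = dataset$id[i])
  })
  names(out) <- dataset$id
  out
}

#' Export sentences in text-corpus format
#'
#' One sentence per line, words separated by single spaces — the
#' conventional input format of text embedding trainers.
#'
#' @param sentences List of word vectors (from [corpus_sentences()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sentences <- function(sentences, path) {
  writeLines(vapply(sentences, paste, character(1L), collapse = " "), path)
  invisible(path)
}
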