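#' Specification for a synthetic promoter benchmark
#'
#' Describes a two-layer fixture dataset that emulates sigma70 promoter
#' architecture: fixed-length uniform-ACGT background sequences in which
#' positives carry degenerate consensus motifs (a -35-like `TTGACA` and a
#' -10-like `TATAAT` box by default) and promoter *strength* is encoded as
#' motif fidelity — strong promoters are corrupted at
#' `per_position_mutation_rate`, weak promoters at
#' `per_position_mutation_rate + strength_mutation_gap`.
#'
#' @param n_pos,n_neg Number of positive (promoter) and negative
#'   (background) sequences.
#' @param length Sequence length in nucleotides (default 81).
#' @param motifs List of `list(consensus =, offset =)` entries; `offset`
#'   is the 1-based start position of the consensus within the sequence.
#' @param per_position_mutation_rate Probability that each motif position
#'   of a *strong* promoter is replaced by one of the three other bases.
#' @param strong_fraction Fraction of positives labeled strong.
#' @param strength_mutation_gap Extra per-position mutation probability
#'   applied to weak promoters.
#' @param gc_bias Optional GC fraction of the background (default `NULL`
#'   = uniform base composition).
#' @param seed Integer seed; identical spec + seed reproduce the dataset
#'   byte for byte.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_pos, n_neg, length = 81,
                           motifs = list(list(consensus = "TTGACA", offset = 11),
                                         list(consensus = "TATAAT", offset = 36)),
                           per_position_mutation_rate = 0.05,
                           strong_fraction = 0.47,
                           strength_mutation_gap = 0.10,
                           gc_bias = NULL,
                           seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0, length >= 1,
            per_position_mutation_rate >= 0, per_position_mutation_rate <= 1,
            strong_fraction >= 0, strong_fraction <= 1,
            strength_mutation_gap >= 0,
            per_position_mutation_rate + strength_mutation_gap <= 1)
  for (m in motifs) {
    stopifnot(is.character(m$consensus), m$offset >= 1)
    if (m$offset + nchar(m$consensus) - 1L > length) {
      stop(sprintf("motif '%s' at offset %d overruns sequence length %d",
                   m$consensus, m$offset, length), call. = FALSE)
    }
    if (grepl("[^ACGT]", m$consensus)) {
      stop("motif consensus must be over A/C/G/T", call. = FALSE)
    }
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length), motifs = motifs,
                 per_position_mutation_rate = per_position_mutation_rate,
                 strong_fraction = strong_fraction,
                 strength_mutation_gap = strength_mutation_gap,
                 gc_bias = gc_bias, seed = as.integer(seed)),
            class = "synthetic_spec")
}

base_probs <- function(spec) {
  if (is.null(spec$gc_bias)) rep(0.25, 4)
  else c((1 - spec$gc_bias) / 2, spec$gc_bias / 2,
         spec$gc_bias / 2, (1 - spec$gc_bias) / 2)  # A C G T
}

random_background <- function(n, len, probs) {
  if (n == 0L) return(character())
  mat <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE, prob = probs),
                nrow = n)
  apply(mat, 1L, paste, collapse = "")
}

plant_motifs <- function(seqs, spec, mut_rate) {
  if (length(seqs) == 0L) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (m in spec$motifs) {
    consensus <- strsplit(m$consensus, "", fixed = TRUE)[[1L]]
    pos <- m$offset + seq_along(consensus) - 1L
    for (i in seq_along(chars)) {
      written <- consensus
      mutate <- stats::runif(length(written)) < mut_rate
      if (any(mutate)) {
        for (j in which(mutate)) {
          written[j] <- sample(setdiff(c("A", "C", "G", "T"), consensus[j]), 1L)
        }
      }
      chars[[i]][pos] <- written
    }
  }
  vapply(chars, paste, character(1L), collapse = "")
}

#' Generate a synthetic two-layer promoter benchmark
#'
#' Positives are background sequences with each motif written at its
#' offset and then corrupted position-wise (strong promoters at the base
#' mutation rate, weak promoters at rate + gap); negatives are pure
#' background.  Layer 1 contains positives and negatives
#' (promoter/non-promoter); layer 2 contains the positives only,
#' relabeled strong/weak.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `layer1` and `layer2` (both
#'   `prom_dataset`s) and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    probs <- base_probs(spec)
    n_strong <- round(spec$n_pos * spec$strong_fraction)
    n_weak <- spec$n_pos - n_strong
    strong_bg <- random_background(n_strong, spec$length, probs)
    weak_bg <- random_background(n_weak, spec$length, probs)
    neg <- random_background(spec$n_neg, spec$length, probs)
    strong <- plant_motifs(strong_bg, spec, spec$per_position_mutation_rate)
    weak <- plant_motifs(weak_bg, spec,
                         spec$per_position_mutation_rate + spec$strength_mutation_gap)
    pos_id <- c(if (n_strong > 0L) sprintf("pos_strong_%04d", seq_len(n_strong)),
                if (n_weak > 0L) sprintf("pos_weak_%04d", seq_len(n_weak)))
    neg_id <- if (spec$n_neg > 0L) sprintf("neg_%04d", seq_len(spec$n_neg)) else character()
    layer1 <- new_dataset(id = c(pos_id, neg_id),
                          bases = c(strong, weak, neg),
                          label = c(rep("promoter", spec$n_pos),
                                    rep("non-promoter", spec$n_neg)),
                          layer = "layer1")
    layer2 <- new_dataset(id = pos_id,
                          bases = c(strong, weak),
                          label = c(rep("strong", n_strong), rep("weak", n_weak)),
                          layer = "layer2")
    list(layer1 = layer1, layer2 = layer2, spec = spec)
  })
}

#' Motif fidelity of a sequence under a synthetic spec
#'
#' Fraction of motif positions (pooled over all motifs in the spec) at
#' which the sequence matches the consensus.
#'
#' @param bases A sequence string of length `spec$length`, or a
#'   one-row slice of a `prom_dataset` (its `bases` column is used).
#' @param spec The [synthetic_spec()] the sequence was generated under.
#' @return Fraction in \[0, 1\].
#' @export
motif_fidelity <- function(bases, spec) {
  if (is.data.frame(bases)) bases <- bases$bases
  stopifnot(length(bases) >= 1L)
  vapply(bases, function(s) {
    if (nchar(s) != spec$length) {
      stop(sprintf("sequence length %d does not match spec length %d",
                   nchar(s), spec$length), call. = FALSE)
    }
    match <- 0L
    total <- 0L
    for (m in spec$motifs) {
      consensus <- strsplit(m$consensus, "", fixed = TRUE)[[1L]]
      got <- strsplit(substr(s, m$offset, m$offset + length(consensus) - 1L),
                      "", fixed = TRUE)[[1L]]
      match <- match + sum(got == consensus)
      total <- total + length(consensus)
    }
    match / total
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Write a synthetic benchmark as FASTA pairs plus a JSON sidecar
#'
#' Emits `layer1_pos.fasta`, `layer1_neg.fasta`, `layer2_pos.fasta`
#' (strong), `layer2_neg.fasta` (weak) and `spec.json` under `dir`.
#'
#' @param sim Result of [generate_synthetic()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  l1 <- sim$layer1; l2 <- sim$layer2
  paths <- c(
    layer1_pos = file.path(dir, "layer1_pos.fasta"),
    layer1_neg = file.path(dir, "layer1_neg.fasta"),
    layer2_pos = file.path(dir, "layer2_pos.fasta"),
    layer2_neg = file.path(dir, "layer2_neg.fasta"),
    spec = file.path(dir, "spec.json")
  )
  write_fasta(l1[l1$label == "promoter", , drop = FALSE], paths["layer1_pos"])
  write_fasta(l1[l1$label == "non-promoter", , drop = FALSE], paths["layer1_neg"])
  write_fasta(l2[l2$label == "strong", , drop = FALSE], paths["layer2_pos"])
  write_fasta(l2[l2$label == "weak", , drop = FALSE], paths["layer2_neg"])
  spec <- sim$spec
  spec_json <- list(n_pos = spec$n_pos, n_neg = spec$n_neg, length = spec$length,
                    motifs = lapply(spec$motifs, function(m)
                      list(consensus = m$consensus, offset = m$offset)),
                    per_position_mutation_rate = spec$per_position_mutation_rate,
                    strong_fraction = spec$strong_fraction,
                    strength_mutation_gap = spec$strength_mutation_gap,
                    gc_bias = spec$gc_bias, seed = spec$seed)
  jsonlite::write_json(spec_json, paths["spec"], auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(paths)
}
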