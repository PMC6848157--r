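#' @useDynLib promlex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pnorm predict rbinom sd
#' @importFrom utils head modifyList
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

LAYER_CLASSES <- list(
  layer1 = c(negative = "non-promoter", positive = "promoter"),
  layer2 = c(negative = "weak",         positive = "strong")
)

#' Positive class label of a classification layer
#'
#' Layer 1 separates promoters from non-promoters (positive class
#' `"promoter"`); layer 2 separates strong from weak promoters (positive
#' class `"strong"`).
#'
#' @param layer `"layer1"` or `"layer2"`.
#' @return Character scalar, the positive class label.
#' @export
positive_class <- function(layer) {
  layer <- match.arg(layer, c("layer1", "layer2"))
  unname(LAYER_CLASSES[[layer]]["positive"])
}

## run expr under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

validate_bases <- function(bases, ids) {
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), bases)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(bases[i], regexpr("[^ACGTN]", bases[i]))
    stop(sprintf("illegal character '%s' in record '%s' (alphabet is A/C/G/T/N)",
                 ch, ids[i]), call. = FALSE)
  }
  if (any(!nzchar(bases))) {
    stop(sprintf("empty sequence for record '%s'", ids[which(!nzchar(bases))[1L]]),
         call. = FALSE)
  }
  invisible(TRUE)
}

new_dataset <- function(id, bases, label, layer) {
  df <- data.frame(id = as.character(id), bases = toupper(as.character(bases)),
                   label = as.character(label), stringsAsFactors = FALSE)
  validate_bases(df$bases, df$id)
  if (!is.na(layer)) {
    admissible <- unname(LAYER_CLASSES[[layer]])
    bad <- !df$label %in% admissible
    if (any(bad)) {
      stop(sprintf("label '%s' not admissible for %s (expected one of: %s)",
                   df$label[which(bad)[1L]], layer,
                   paste(admissible, collapse = ", ")), call. = FALSE)
    }
  }
  structure(df, layer = layer, class = c("prom_dataset", "data.frame"))
}

#' Per-class record counts of a dataset
#'
#' @param dataset A `prom_dataset` as returned by [load_benchmark()] or
#'   [generate_synthetic()].
#' @return Named integer vector of counts per class label.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "prom_dataset"))
  table(factor(dataset$label)) |> c()
}

#' @export
print.prom_dataset <- function(x, ...) {
  cat(sprintf("<prom_dataset> %d records, layer = %s\n",
              nrow(x), attr(x, "layer") %||% "NA"))
  if (nrow(x) > 0L) {
    cc <- class_counts(x)
    cat("  classes:", paste(sprintf("%s = %d", names(cc), cc), collapse = ", "), "\n")
    cat("  lengths:", paste(range(nchar(x$bases)), collapse = "-"), "nt\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Read a FASTA file of DNA sequences
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; multi-line
#' bodies are joined and bases are uppercased.  Records must be restricted
#' to the A/C/G/T/N alphabet; anything else is rejected with the offending
#' character and record id, and sequence data before the first header is a
#' parse error naming the line.
#'
#' @param path Path to a FASTA file (headers start with `>`).
#' @return A data frame with columns `id` and `bases`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(), bases = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop(sprintf("malformed FASTA: sequence data before first header at line %d of %s",
                 nonblank[1L], path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  id <- sub("\\s.*$", "", names(set))
  bases <- toupper(as.character(set))
  names(bases) <- NULL
  validate_bases(bases, id)
  data.frame(id = id, bases = bases, stringsAsFactors = FALSE)
}

#' Read one-sequence-per-line text
#'
#' @param path Path to a plain-text file, one uppercase/lowercase DNA
#'   sequence per line; blank lines are skipped.
#' @param prefix Identifier prefix; records are named `<prefix>1`,
#'   `<prefix>2`, ...
#' @return A data frame with columns `id` and `bases`.
#' @export
read_seq_lines <- function(path, prefix = "seq") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  id <- sprintf("%s%d", prefix, seq_along(lines))  # length 0 stays length 0
  bases <- toupper(lines)
  validate_bases(bases, id)
  data.frame(id = id, bases = bases, stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records A data frame with columns `id` and `bases` (a
#'   `prom_dataset` works as-is; labels are not written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$bases)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

read_any_sequences <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) > 0L && startsWith(trimws(first[1L]), ">")) {
    read_fasta(path)
  } else {
    read_seq_lines(path, prefix = paste0(tools::file_path_sans_ext(basename(path)), "_"))
  }
}

#' Load a two-file benchmark dataset
#'
#' Reads a positives file and a negatives file (FASTA or
#' one-sequence-per-line text, auto-detected) and assigns labels by source
#' file: promoter/non-promoter for layer 1, strong/weak for layer 2.
#' Record order is preserved; an optional seed applies one explicit,
#' reproducible shuffle.
#'
#' @param positives,negatives File paths for the two classes.
#' @param layer `"layer1"` or `"layer2"`.
#' @param seed Optional integer; when given, records are shuffled once,
#'   deterministically.
#' @return A `prom_dataset`.
#' @export
load_benchmark <- function(positives, negatives, layer = c("layer1", "layer2"),
                           seed = NULL) {
  layer <- match.arg(layer)
  pos <- read_any_sequences(positives)
  neg <- read_any_sequences(negatives)
  if (nrow(pos) == 0L) stop("positives file contains no sequences", call. = FALSE)
  if (nrow(neg) == 0L) stop("negatives file contains no sequences", call. = FALSE)
  classes <- LAYER_CLASSES[[layer]]
  id <- c(pos$id, neg$id)
  if (anyDuplicated(id)) {
    warning("duplicate ids across class files; suffixing to make them unique")
    id <- make.unique(id, sep = "_dup")
  }
  ds <- new_dataset(id = id,
                    bases = c(pos$bases, neg$bases),
                    label = c(rep(unname(classes["positive"]), nrow(pos)),
                              rep(unname(classes["negative"]), nrow(neg))),
                    layer = layer)
  if (!is.null(seed)) {
    perm <- with_local_seed(as.integer(seed), sample.int(nrow(ds)))
    ds <- ds[perm, , drop = FALSE]
    rownames(ds) <- NULL
    ds <- structure(ds, layer = layer, class = c("prom_dataset", "data.frame"))
  }
  ds
}

#' Construct a feature table
#'
#' A feature table couples a numeric samples-by-features matrix with sample
#' ids and binary labels; it is the interchange object between the
#' embedding, feature-selection and model modules.
#'
#' @param x Numeric matrix, one row per sample.
#' @param labels Binary labels, one per row (character, factor or 0/1).
#' @param sample_ids Optional sample identifiers (default: rownames or
#'   `sample<i>`).
#' @param feature_names Optional feature names (default: colnames or
#'   `feature_<j>`).
#' @param positive Label value treated as the positive class; default is
#'   the last level in sorted order.
#' @return A `feature_table` object.
#' @export
feature_table <- function(x, labels, sample_ids = NULL, feature_names = NULL,
                          positive = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(labels) != nrow(x)) {
    stop("row count must equal label count", call. = FALSE)
  }
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels contain missing values", call. = FALSE)
  sample_ids <- sample_ids %||% rownames(x) %||% paste0("sample", seq_len(nrow(x)))
  feature_names <- feature_names %||% colnames(x) %||%
    paste0("feature_", seq_len(ncol(x)))
  if (length(feature_names) != ncol(x)) {
    stop("feature_names length must equal column count", call. = FALSE)
  }
  dimnames(x) <- list(NULL, feature_names)
  classes <- sort(unique(labels))
  if (length(classes) > 2L) stop("labels must be binary", call. = FALSE)
  positive <- positive %||% classes[length(classes)]
  structure(list(x = x, labels = labels, sample_ids = as.character(sample_ids),
                 feature_names = feature_names, positive = positive),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; positive class = '%s'\n",
              nrow(x$x), ncol(x$x), x$positive))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

subset_table <- function(table, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(table$x))
  cols <- cols %||% seq_len(ncol(table$x))
  feature_table(table$x[rows, cols, drop = FALSE],
                labels = table$labels[rows],
                sample_ids = table$sample_ids[rows],
                feature_names = table$feature_names[cols],
                positive = table$positive)
}

#' Write a feature table as TSV
#'
#' Layout: header row of feature names, first column `sample_id`, last
#' column `label`.  Values are written with round-trip precision so that
#' [read_feature_table()] reproduces the table exactly.
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.table::data.table(sample_id = table$sample_ids)
  ## %.17g guarantees the read-back double is bit-identical
  for (j in seq_len(ncol(table$x))) {
    df[[table$feature_names[j]]] <- sprintf("%.17g", table$x[, j])
  }
  df[["label"]] <- table$labels
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @param positive Positive class label passed on to [feature_table()].
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, positive = NULL) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("sample_id", "label")))
  fcols <- setdiff(names(df), c("sample_id", "label"))
  feature_table(as.matrix(df[, fcols, drop = FALSE]),
                labels = as.character(df$label),
                sample_ids = as.character(df$sample_id),
                feature_names = fcols,
                positive = positive)
}

#' Turn a labeled dataset plus feature matrix into a feature table
#'
#' @param dataset A `prom_dataset`.
#' @param x Feature matrix with one row per dataset record.
#' @return A `feature_table` whose positive class follows the dataset layer.
#' @export
dataset_feature_table <- function(dataset, x) {
  layer <- attr(dataset, "layer")
  feature_table(x, labels = dataset$label, sample_ids = dataset$id,
                positive = if (!is.null(layer) && !is.na(layer)) positive_class(layer) else NULL)
}
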