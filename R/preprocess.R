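# Phase 1: overlapping k-mer splitting and vocabulary tokenization.

#' k-mer splitting configuration
#'
#' @param k Window length in bases; the library accepts 1..8, the pipeline
#'   restricts the choice to 2..4 (single bases carry no context and
#'   prediction quality drops beyond 4-mers).
#' @param stride Step between window starts; 1 (overlapping windows, the
#'   default) reproduces the canonical splitting where a length-L sequence
#'   yields L - k + 1 k-mers, repeats retained.
#' @return A config list of class `gmean_kmer_config`.
#' @export
kmer_config <- function(k = 2L, stride = 1L) {
  stopifnot(is_count(k), is_count(stride))
  if (k > 8L) stopf("kmer_config: k must be in 1..8, got %d", k)
  structure(list(k = as.integer(k), stride = as.integer(stride)),
            class = "gmean_kmer_config")
}

#' Split a DNA sequence into overlapping k-mers
#'
#' Windows are emitted in sequence order, duplicates retained, and
#' normalized to lower case (tokenizer convention: vocabularies are
#' lower-case while input sequences are upper-case).
#'
#' @param sequence A single DNA string.
#' @param config A [kmer_config()]; or pass `k` / `stride` directly.
#' @param k,stride Used when `config` is missing.
#' @param strict When the sequence is shorter than `k`: error (default) or
#'   return an empty vector (`strict = FALSE`).
#' @return Character vector of k-mers, length `floor((len - k)/stride) + 1`.
#' @examples
#' kmerize("CCTCCCGAGAGA", k = 2)
#' @export
kmerize <- function(sequence, config = NULL, k = 2L, stride = 1L,
                    strict = TRUE) {
  if (is.null(config)) config <- kmer_config(k, stride)
  stopifnot(length(sequence) == 1L, is.character(sequence))
  s <- tolower(sequence)
  len <- nchar(s)
  if (len < config$k) {
    if (strict) {
      stopf("kmerize: sequence of length %d is shorter than k = %d",
            len, config$k)
    }
    return(character(0))
  }
  starts <- seq.int(1L, len - config$k + 1L, by = config$stride)
  substring(s, starts, starts + config$k - 1L)
}

#' Build a k-mer vocabulary from a corpus
#'
#' Assigns contiguous integer ids `1..V` to the distinct k-mers observed in
#' the corpus; id 0 is reserved for padding and (under the permissive
#' policy) unknown k-mers, and never maps to a k-mer. Under
#' `ordering = "frequency_desc"` (default) ids follow decreasing corpus
#' frequency with lexicographic tie-break; `"lexicographic"` gives a
#' corpus-independent ordering.
#'
#' @param corpus Character vector of DNA sequences, or a sequence record
#'   data frame (its `sequence` column is used).
#' @param config A [kmer_config()].
#' @param ordering Id assignment rule.
#' @return An object of class `gmean_vocabulary`: list with `k`, `stride`,
#'   `kmers` (character, position = id), `index_of` (named integer lookup)
#'   and `ordering`.
#' @export
build_vocabulary <- function(corpus, config = kmer_config(),
                             ordering = c("frequency_desc", "lexicographic")) {
  ordering <- match.arg(ordering)
  if (is.data.frame(corpus)) corpus <- corpus$sequence
  if (length(corpus) == 0L) stopf("build_vocabulary: empty corpus")
  counts <- table(unlist(lapply(corpus, kmerize, config = config),
                         use.names = FALSE))
  kmers <- names(counts)
  ord <- if (ordering == "frequency_desc") {
    order(-as.numeric(counts), kmers, method = "radix")
  } else {
    order(kmers, method = "radix")
  }
  kmers <- kmers[ord]
  structure(list(k = config$k, stride = config$stride, kmers = kmers,
                 index_of = stats::setNames(seq_along(kmers), kmers),
                 ordering = ordering),
            class = "gmean_vocabulary")
}

#' Assemble a vocabulary from an explicit k-mer -> id mapping
#'
#' Used to reinstate a previously saved (or externally defined) vocabulary;
#' ids must be a permutation of `1..V`.
#'
#' @param kmers Character vector of k-mers, all of one length.
#' @param ids Integer ids, a permutation of `seq_along(kmers)`.
#' @return A `gmean_vocabulary`.
#' @export
vocabulary_from_map <- function(kmers, ids = seq_along(kmers)) {
  kmers <- tolower(as.character(kmers))
  ids <- as.integer(ids)
  stopifnot(length(kmers) == length(ids), !anyDuplicated(kmers))
  if (!setequal(ids, seq_along(kmers))) {
    stopf("vocabulary ids must be a permutation of 1..%d", length(kmers))
  }
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stopf("all vocabulary k-mers must have equal length")
  ordered <- character(length(kmers))
  ordered[ids] <- kmers
  structure(list(k = as.integer(k), stride = 1L, kmers = ordered,
                 index_of = stats::setNames(ids, kmers),
                 ordering = "explicit"),
            class = "gmean_vocabulary")
}

#' @export
print.gmean_vocabulary <- function(x, ...) {
  cat(sprintf("k-mer vocabulary: k = %d, %d entries (%s ordering)\n",
              x$k, length(x$kmers), x$ordering))
  show <- utils::head(x$kmers, 8L)
  cat("  ", paste(sprintf("'%s':%d", show, x$index_of[show]),
                  collapse = " "),
      if (length(x$kmers) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Save / load a vocabulary as a two-column text table
#'
#' The on-disk form is a tab-separated `kmer<TAB>id` table in id order, so a
#' prediction run can reuse exactly the vocabulary of a training run.
#'
#' @param vocab A `gmean_vocabulary`.
#' @param path File path.
#' @return `path` (write) or the reinstated vocabulary (read).
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(data.frame(kmer = vocab$kmers,
                                id = seq_along(vocab$kmers)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer"))
  vocabulary_from_map(tab$kmer, tab$id)
}

#' Tokenize a DNA sequence against a vocabulary
#'
#' Maps each overlapping k-mer to its integer id. Under the default strict
#' policy an unseen k-mer is an error naming the k-mer and its position;
#' under `unknown = "mask"` it maps to the reserved id 0.
#'
#' @param sequence A single DNA string.
#' @param vocab A `gmean_vocabulary`.
#' @param unknown `"error"` (default) or `"mask"`.
#' @return Integer vector of token ids.
#' @examples
#' v <- vocabulary_from_map(c("gg", "cc", "gc", "ct", "tg", "ag", "ca", "tc",
#'                            "ga", "tt", "aa", "gt", "ac", "cg", "at", "ta"))
#' tokenize("CCTCCCGAGAGA", v)
#' @export
tokenize <- function(sequence, vocab, unknown = c("error", "mask")) {
  unknown <- match.arg(unknown)
  stopifnot(inherits(vocab, "gmean_vocabulary"))
  kmers <- kmerize(sequence, kmer_config(vocab$k, vocab$stride))
  ids <- vocab$index_of[kmers]
  miss <- is.na(ids)
  if (any(miss)) {
    if (unknown == "error") {
      pos <- which(miss)[1L]
      stopf("tokenize: k-mer '%s' at position %d is not in the vocabulary",
            kmers[pos], pos)
    }
    ids[miss] <- 0L
  }
  as.integer(unname(ids))
}

#' Encode a record collection as a padded token matrix
#'
#' Rows are post-padded with the reserved id 0 to the length of the longest
#' tokenized sequence in the collection; true token counts are kept in
#' `lengths` and the label vector stays aligned with the rows.
#'
#' @param records Sequence record data frame.
#' @param vocab A `gmean_vocabulary`.
#' @param unknown Passed to [tokenize()]; errors gain the record id.
#' @return An object of class `gmean_tokens`: list with `tokens`
#'   (n x max_len integer matrix), `lengths`, `labels` (integer, `NA` when
#'   unlabelled), `ids` and `vocab`.
#' @export
encode_dataset <- function(records, vocab, unknown = c("error", "mask")) {
  unknown <- match.arg(unknown)
  n <- nrow(records)
  token_list <- vector("list", n)
  for (i in seq_len(n)) {
    token_list[[i]] <- tryCatch(
      tokenize(records$sequence[i], vocab, unknown),
      error = function(e) stopf("encode_dataset: record '%s': %s",
                                records$id[i], conditionMessage(e)))
  }
  lens <- lengths(token_list)
  width <- if (n) max(lens) else 0L
  tokens <- matrix(0L, nrow = n, ncol = width)
  for (i in seq_len(n)) {
    if (lens[i]) tokens[i, seq_len(lens[i])] <- token_list[[i]]
  }
  structure(list(tokens = tokens, lengths = as.integer(lens),
                 labels = records$label, ids = records$id, vocab = vocab),
            class = "gmean_tokens")
}

#' @export
print.gmean_tokens <- function(x, ...) {
  cat(sprintf("tokenized dataset: %d sequences x %d tokens (k = %d, V = %d)\n",
              nrow(x$tokens), ncol(x$tokens), x$vocab$k,
              length(x$vocab$kmers)))
  if (!all(is.na(x$labels))) {
    tab <- table(x$labels, useNA = "no")
    cat("  labels:", paste(sprintf("%s: %d", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}
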