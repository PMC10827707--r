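# Sequence datasets: construction, CSV/FASTA I/O, the 4:1 split protocol and
# the synthetic two-class motif-planted generator.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Construct a validated collection of sequence records
#'
#' A sequence record collection is a data frame with columns `id` (short
#' unique string), `sequence` (DNA string over A/C/G/T) and `label` (0, 1 or
#' `NA` when unlabelled). All user-facing functions in the package accept and
#' return this shape.
#'
#' @param sequence Character vector of DNA sequences. Normalized to upper
#'   case.
#' @param label Optional integer vector of class labels in `{0, 1}`; `NA`
#'   marks an unlabelled record. Recycled `NA` when omitted.
#' @param id Optional character vector of record ids; defaults to
#'   `seq_1 ... seq_n` in input order.
#' @param alphabet Either `"strict"` (default; any character outside
#'   A/C/G/T is an error) or `"permissive"` (other IUPAC characters are kept
#'   and map to the unknown token during tokenization).
#' @return A `data.frame` with columns `id`, `sequence`, `label`.
#' @examples
#' sequence_records(c("CCCCACCCGT", "CCCCTCACCC"), label = c(1, 0))
#' @export
sequence_records <- function(sequence, label = NULL, id = NULL,
                             alphabet = c("strict", "permissive")) {
  alphabet <- match.arg(alphabet)
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  if (n > 0L && any(!nzchar(sequence))) {
    stopf("sequence_records: empty sequence at row %d",
          which(!nzchar(sequence))[1L])
  }
  if (alphabet == "strict") {
    bad <- grepl("[^ACGT]", sequence)
    if (any(bad)) {
      row <- which(bad)[1L]
      offending <- sub(".*?([^ACGT]).*", "\\1", sequence[row])
      stopf("sequence_records: character '%s' outside alphabet {A,C,G,T} at row %d",
            offending, row)
    }
  }
  if (is.null(label)) {
    label <- rep(NA_integer_, n)
  } else {
    label <- suppressWarnings(as.integer(label))
    ok <- is.na(label) | label %in% c(0L, 1L)
    if (!all(ok)) {
      stopf("sequence_records: label at row %d is not 0, 1 or NA",
            which(!ok)[1L])
    }
    if (length(label) != n) stopf("sequence_records: %d labels for %d sequences",
                                  length(label), n)
  }
  if (is.null(id)) id <- if (n) sprintf("seq_%d", seq_len(n)) else character(0)
  id <- as.character(id)
  if (length(id) != n) stopf("sequence_records: %d ids for %d sequences",
                             length(id), n)
  data.frame(id = id, sequence = sequence, label = label,
             stringsAsFactors = FALSE)
}

#' Read a sequence dataset from CSV
#'
#' Expects the two-column layout `sequence,label` (one column when
#' `has_labels = FALSE`). A header row is auto-detected: a first row whose
#' sequence field contains characters outside the DNA alphabet, or whose
#' label field is not 0/1, is treated as a header.
#'
#' @param path Path to a CSV file.
#' @param has_labels Logical; does the file carry a label column?
#' @inheritParams sequence_records
#' @return A sequence record data frame (see [sequence_records()]); file
#'   order is preserved and ids are assigned positionally.
#' @export
read_sequence_csv <- function(path, has_labels = TRUE,
                              alphabet = c("strict", "permissive")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("read_sequence_csv: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(sequence_records(character(0)))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  ncol_expect <- if (has_labels) 2L else 1L
  widths <- lengths(fields)
  if (any(widths != ncol_expect)) {
    stopf("read_sequence_csv: row %d has %d fields, expected %d",
          which(widths != ncol_expect)[1L], widths[widths != ncol_expect][1L],
          ncol_expect)
  }
  seqs <- trimws(vapply(fields, `[[`, "", 1L))
  labs <- if (has_labels) trimws(vapply(fields, `[[`, "", 2L)) else NULL
  # Header detection on the first row only.
  first_is_header <- grepl("[^ACGTN]", toupper(seqs[1L])) ||
    (has_labels && !labs[1L] %in% c("0", "1"))
  if (first_is_header) {
    seqs <- seqs[-1L]
    if (has_labels) labs <- labs[-1L]
  }
  if (length(seqs) == 0L) return(sequence_records(character(0)))
  if (has_labels) {
    bad <- !labs %in% c("0", "1")
    if (any(bad)) {
      stopf("read_sequence_csv: malformed label '%s' at data row %d (must be 0 or 1)",
            labs[which(bad)[1L]], which(bad)[1L])
    }
  }
  sequence_records(seqs,
                   label = if (has_labels) as.integer(labs) else NULL,
                   alphabet = alphabet)
}

#' Write a sequence dataset to CSV
#'
#' Emits the `sequence,label` layout read by [read_sequence_csv()]; the label
#' column is dropped when every record is unlabelled or `labels = FALSE`.
#'
#' @param records A sequence record data frame.
#' @param path Output path.
#' @param labels Include the label column when labels are present?
#' @param header Write a `sequence,label` header row?
#' @return `path`, invisibly.
#' @export
write_sequence_csv <- function(records, path, labels = TRUE, header = TRUE) {
  with_labels <- labels && any(!is.na(records$label))
  con <- file(path, "w")
  on.exit(close(con))
  if (with_labels) {
    if (header) writeLines("sequence,label", con)
    writeLines(paste(records$sequence, records$label, sep = ","), con)
  } else {
    if (header) writeLines("sequence", con)
    writeLines(records$sequence, con)
  }
  invisible(path)
}

#' Read sequences from FASTA, with labels carried in headers
#'
#' Labels are parsed from a `|label=<0|1>` suffix on the FASTA header when
#' present. Requires the Biostrings package.
#'
#' @inheritParams read_sequence_csv
#' @return A sequence record data frame.
#' @export
read_sequence_fasta <- function(path, alphabet = c("strict", "permissive")) {
  alphabet <- match.arg(alphabet)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stopf("read_sequence_fasta requires the Biostrings package")
  }
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  labs <- rep(NA_integer_, length(ss))
  has <- grepl("\\|label=[01]\\b", headers)
  labs[has] <- as.integer(sub(".*\\|label=([01]).*", "\\1", headers[has]))
  ids <- sub("\\|label=[01].*", "", headers)
  ids <- sub("\\s.*$", "", ids)
  sequence_records(as.character(ss), label = labs, id = ids,
                   alphabet = alphabet)
}

#' Write sequences to FASTA with labels in headers
#'
#' @inheritParams write_sequence_csv
#' @return `path`, invisibly.
#' @export
write_sequence_fasta <- function(records, path) {
  hdr <- ifelse(is.na(records$label),
                records$id,
                paste0(records$id, "|label=", records$label))
  out <- character(2L * nrow(records))
  out[c(TRUE, FALSE)] <- paste0(">", hdr)
  out[c(FALSE, TRUE)] <- records$sequence
  writeLines(out, path)
  invisible(path)
}

# One stratified split of labelled records into a larger and a smaller part.
# The smaller part gets floor(n * small / (large + small)) records overall,
# allocated across classes by largest remainder so class balance is kept.
partition_records <- function(records, ratio = c(4, 1), seed = 1L,
                              stratified = TRUE) {
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  n <- nrow(records)
  n_small <- floor(n * ratio[2L] / sum(ratio))
  if (n_small < 1L || n - n_small < 1L) {
    stopf("partition_records: %d records cannot be split %s:%s with both parts non-empty",
          n, ratio[1L], ratio[2L])
  }
  idx_small <- with_seed(seed, {
    if (stratified && any(!is.na(records$label))) {
      groups <- split(seq_len(n), records$label)
      quota <- n_small * lengths(groups) / n
      base <- floor(quota)
      short <- n_small - sum(base)
      if (short > 0) {
        top_up <- order(quota - base, decreasing = TRUE)[seq_len(short)]
        base[top_up] <- base[top_up] + 1L
      }
      unlist(Map(function(ix, k) if (k > 0) sample(ix, k) else integer(0),
                 groups, base), use.names = FALSE)
    } else {
      sample(n, n_small)
    }
  })
  idx_small <- sort(idx_small)
  list(large = records[setdiff(seq_len(n), idx_small), , drop = FALSE],
       small = records[idx_small, , drop = FALSE])
}

#' Split labelled records into train / validation / held-out test sets
#'
#' Applies the two-stage protocol: the input is first divided into a learning
#' and a testing pool at `learn_test_ratio` (default 4:1), then the learning
#' pool into training and validation sets at `train_val_ratio` (default 4:1).
#' Splits are stratified by label so class balance is preserved, and the
#' smaller part of each division is floored. The test records are stripped of
#' their labels (the prediction phase treats them as unlabelled); the true
#' labels are retained out-of-band in `test_labels` for evaluation only.
#'
#' With 20,000 balanced records the default ratios give a 16,000-record
#' learning pool (12,800 train / 3,200 validation) and 4,000 test records.
#'
#' @param records Labelled sequence record data frame (no `NA` labels).
#' @param learn_test_ratio,train_val_ratio Length-2 positive numeric ratios.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `gmean_split`: a list with `train`,
#'   `validation`, `test_unlabelled` (record data frames, pairwise disjoint,
#'   union = input), `test_labels` (integer vector aligned with
#'   `test_unlabelled`), plus the ratios and seed.
#' @export
split_dataset <- function(records, learn_test_ratio = c(4, 1),
                          train_val_ratio = c(4, 1), seed = 1L) {
  if (nrow(records) == 0L) stopf("split_dataset: no records")
  if (any(is.na(records$label))) {
    stopf("split_dataset: all records must be labelled")
  }
  lt <- partition_records(records, learn_test_ratio,
                          seed = derive_seed(seed, 1L))
  tv <- partition_records(lt$large, train_val_ratio,
                          seed = derive_seed(seed, 2L))
  test <- lt$small
  test_labels <- test$label
  test$label <- NA_integer_
  structure(list(train = tv$large,
                 validation = tv$small,
                 test_unlabelled = test,
                 test_labels = test_labels,
                 learn_test_ratio = learn_test_ratio,
                 train_val_ratio = train_val_ratio,
                 seed = seed),
            class = "gmean_split")
}

#' @export
print.gmean_split <- function(x, ...) {
  cat(sprintf("Sequence dataset split (seed %s)\n", format(x$seed)))
  cat(sprintf("  train:          %6d records\n", nrow(x$train)))
  cat(sprintf("  validation:     %6d records\n", nrow(x$validation)))
  cat(sprintf("  test (held-out):%6d records (labels kept out-of-band)\n",
              nrow(x$test_unlabelled)))
  invisible(x)
}

#' Configuration for the synthetic two-class sequence generator
#'
#' The generator emulates a balanced two-class TF-binding-site dataset:
#' i.i.d. background bases drawn from `background`, with a class-specific
#' motif planted at a uniform random position in a fraction
#' `insertion_prob` of each class's sequences. Motifs may be consensus
#' strings or 4 x L position-weight matrices (rows A, C, G, T).
#'
#' Defaults plant two 8-base consensus motifs at Hamming distance 6 in 90%
#' of sequences of length 100 over a uniform background; this produces a
#' strongly separable, balanced dataset.
#'
#' @param n_per_class Sequences per class.
#' @param seq_length Sequence length in bases (all sequences equal length).
#' @param motif_class0,motif_class1 Consensus string over A/C/G/T or a
#'   4 x L probability matrix with rownames `A,C,G,T` (columns sum to 1).
#' @param insertion_prob Probability that a sequence of a class carries its
#'   motif; scalar or length-2 vector `(class0, class1)`.
#' @param background Length-4 base-composition vector `(A, C, G, T)`,
#'   non-negative, summing to 1.
#' @param seed Integer seed; generation is byte-identical given the seed.
#' @return A validated config list of class `gmean_synth_config`.
#' @export
synthetic_config <- function(n_per_class = 2000L,
                             seq_length = 100L,
                             motif_class0 = "TGACGTCA",
                             motif_class1 = "GGGACTTT",
                             insertion_prob = 0.9,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                             seed = 1L) {
  stopifnot(is_count(n_per_class), is_count(seq_length))
  if (length(insertion_prob) == 1L) insertion_prob <- rep(insertion_prob, 2L)
  stopifnot(length(insertion_prob) == 2L)
  if (any(insertion_prob < 0 | insertion_prob > 1)) {
    stopf("synthetic_config: insertion_prob must lie in [0, 1]")
  }
  background <- as.numeric(background)
  stopifnot(length(background) == 4L)
  if (any(background < 0) || abs(sum(background) - 1) > 1e-9) {
    stopf("synthetic_config: background composition must be non-negative and sum to 1")
  }
  for (m in list(motif_class0, motif_class1)) {
    len <- motif_length(m)
    if (len > seq_length) {
      stopf("synthetic_config: motif of length %d exceeds seq_length %d",
            len, seq_length)
    }
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 seq_length = as.integer(seq_length),
                 motif_class0 = motif_class0,
                 motif_class1 = motif_class1,
                 insertion_prob = insertion_prob,
                 background = background,
                 seed = as.integer(seed)),
            class = "gmean_synth_config")
}

motif_length <- function(motif) {
  if (is.matrix(motif)) {
    if (nrow(motif) != 4L) stopf("PWM motif must have 4 rows (A, C, G, T)")
    ncol(motif)
  } else {
    m <- toupper(as.character(motif))
    if (grepl("[^ACGT]", m)) stopf("consensus motif must be over {A,C,G,T}")
    nchar(m)
  }
}

# Realize one motif instance as a character vector of bases.
draw_motif <- function(motif) {
  if (is.matrix(motif)) {
    apply(motif, 2L, function(p) sample(DNA_ALPHABET, 1L, prob = p))
  } else {
    strsplit(toupper(motif), "")[[1L]]
  }
}

#' Generate a synthetic two-class motif-planted dataset
#'
#' @param config A [synthetic_config()] object (or arguments passed on to
#'   it via `...` when `config` is missing).
#' @param ... Passed to [synthetic_config()] when `config` is missing.
#' @return A labelled sequence record data frame with exactly
#'   `n_per_class` records per class (class 0 block first), ids
#'   `c<class>_<i>`.
#' @examples
#' d <- generate_synthetic(synthetic_config(n_per_class = 5, seq_length = 30,
#'                                          seed = 42))
#' table(d$label)
#' @export
generate_synthetic <- function(config = NULL, ...) {
  if (is.null(config)) config <- synthetic_config(...)
  stopifnot(inherits(config, "gmean_synth_config"))
  with_seed(config$seed, {
    n <- config$n_per_class
    L <- config$seq_length
    make_class <- function(class_label, motif, p_ins) {
      chars <- matrix(sample(DNA_ALPHABET, n * L, replace = TRUE,
                             prob = config$background),
                      nrow = n, ncol = L)
      has_motif <- stats::runif(n) < p_ins
      mlen <- motif_length(motif)
      for (i in which(has_motif)) {
        pos <- sample.int(L - mlen + 1L, 1L)
        chars[i, pos:(pos + mlen - 1L)] <- draw_motif(motif)
      }
      data.frame(id = sprintf("c%d_%05d", class_label, seq_len(n)),
                 sequence = do.call(paste0, as.data.frame(chars)),
                 label = rep(as.integer(class_label), n),
                 stringsAsFactors = FALSE)
    }
    rbind(make_class(0L, config$motif_class0, config$insertion_prob[1L]),
          make_class(1L, config$motif_class1, config$insertion_prob[2L]))
  })
}
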