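# Confusion-matrix accounting and the four performance measures
# (accuracy, precision, recall, F1), reported per class.

check_binary <- function(x, name) {
  if (!all(x %in% c(0L, 1L))) {
    stopf("%s must contain only 0 and 1", name)
  }
}

#' Confusion-matrix cell counts for binary predictions
#'
#' @param y_true,y_pred Equal-length binary vectors (values in `{0, 1}`).
#' @param positive_class Which label is treated as positive (default 1).
#' @return An object of class `gmean_confusion`: list with integers `TP`,
#'   `FP`, `FN`, `TN`, the `positive_class` and total `n`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class = 1L) {
  if (length(y_true) != length(y_pred)) {
    stopf("confusion_counts: lengths differ (%d vs %d)",
          length(y_true), length(y_pred))
  }
  if (length(y_true) < 1L) stopf("confusion_counts: empty input")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  check_binary(y_true, "y_true"); check_binary(y_pred, "y_pred")
  if (!positive_class %in% c(0L, 1L)) {
    stopf("confusion_counts: positive_class must be 0 or 1")
  }
  pos_t <- y_true == positive_class
  pos_p <- y_pred == positive_class
  structure(list(TP = sum(pos_t & pos_p),
                 FP = sum(!pos_t & pos_p),
                 FN = sum(pos_t & !pos_p),
                 TN = sum(!pos_t & !pos_p),
                 positive_class = as.integer(positive_class),
                 n = length(y_true)),
            class = "gmean_confusion")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Implements the standard identities
#' A = (TP + TN) / (TP + FP + FN + TN), P = TP / (TP + FP),
#' R = TP / (TP + FN), F1 = 2PR / (P + R). A ratio with zero denominator is
#' reported as 0 and flagged in `degenerate`.
#'
#' @param counts A [confusion_counts()] object.
#' @return List with `accuracy`, `precision`, `recall`, `f1` (fractions in
#'   `[0, 1]`) and a character vector `degenerate` naming any measures with
#'   zero denominators.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "gmean_confusion"))
  degenerate <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  with(counts, {
    A <- (TP + TN) / (TP + FP + FN + TN)
    P <- ratio(TP, TP + FP, "precision")
    R <- ratio(TP, TP + FN, "recall")
    F1 <- if (P + R > 0) 2 * P * R / (P + R) else {
      degenerate <- c(degenerate, "f1"); 0
    }
    list(accuracy = A, precision = P, recall = R, f1 = F1,
         degenerate = degenerate)
  })
}

#' Per-class evaluation report
#'
#' Builds one row per class, treating that class as positive, with the
#' overall accuracy shared across rows — the layout used to compare
#' predictors per cell-line class. Fractions are kept at full precision; the
#' print method renders percentages (accuracy to 2 d.p., per-class measures
#' to the nearest integer) in the table style of the field.
#'
#' @inheritParams confusion_counts
#' @return An object of class `gmean_report`: data frame with columns
#'   `class`, `support`, `accuracy`, `precision`, `recall`, `f1`,
#'   `degenerate` (flag for rows with undefined ratios or absent classes).
#' @export
class_report <- function(y_true, y_pred) {
  rows <- lapply(c(0L, 1L), function(cls) {
    cc <- confusion_counts(y_true, y_pred, positive_class = cls)
    m <- compute_metrics(cc)
    data.frame(class = cls,
               support = cc$TP + cc$FN,
               accuracy = m$accuracy,
               precision = m$precision,
               recall = m$recall,
               f1 = m$f1,
               degenerate = length(m$degenerate) > 0 || (cc$TP + cc$FN) == 0)
  })
  structure(do.call(rbind, rows), class = c("gmean_report", "data.frame"))
}

#' Render an evaluation report as percentage text
#'
#' @param x A `gmean_report`.
#' @return Character vector of table lines (also used by the print method).
#' @export
format_report <- function(x) {
  lines <- c(sprintf("A (%%): %.2f", 100 * x$accuracy[1L]),
             "class   P (%)   R (%)   F1 (%)  support")
  for (i in seq_len(nrow(x))) {
    lines <- c(lines, sprintf("%5d %7.0f %7.0f %8.0f %8d%s",
                              x$class[i], 100 * x$precision[i],
                              100 * x$recall[i], 100 * x$f1[i],
                              x$support[i],
                              if (x$degenerate[i]) "  [degenerate]" else ""))
  }
  lines
}

#' @export
print.gmean_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Write an evaluation report to CSV
#'
#' @param x A `gmean_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
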