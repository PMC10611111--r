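## Confusion-matrix arithmetic: per-class and combined-positive precision,
## recall, specificity, F1 and balanced accuracy. Fractional counts are
## accepted throughout, because iteration-averaged matrices are fractional
## by nature. Undefined ratios (zero denominators) are reported as NA
## flags, never silently as 0.

#' Confusion matrix from row percentages
#'
#' Converts a row-percentage confusion matrix (rows = actual classes) and
#' the class sizes into fractional counts:
#' `counts[i, j] = size[i] * pct[i, j] / 100`.
#'
#' @param row_pcts 3 x 3 (or k x k) numeric matrix of row percentages.
#' @param class_sizes positive numeric vector of actual-class sizes.
#' @return Object of class `confusion_matrix` (a counts matrix with a
#'   `class_sizes` attribute).
#' @export
confusion_from_percentages <- function(row_pcts, class_sizes) {
  row_pcts <- as.matrix(row_pcts)
  if (any(row_pcts < 0)) stop("negative percentages")
  if (any(class_sizes <= 0)) stop("class sizes must be positive")
  stopifnot(nrow(row_pcts) == ncol(row_pcts),
            length(class_sizes) == nrow(row_pcts))
  counts <- sweep(row_pcts / 100, 1, class_sizes, `*`)
  if (is.null(rownames(counts))) {
    rownames(counts) <- colnames(counts) <-
      if (nrow(counts) == 3) c("EOA", "DCD", "CTRL") else paste0("C", seq_len(nrow(counts)))
  }
  structure(counts, class_sizes = class_sizes, class = c("confusion_matrix", "matrix"))
}

#' Confusion matrix from counts
#'
#' @param counts square matrix of (possibly fractional) counts,
#'   rows = actual, columns = predicted.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  stopifnot(nrow(counts) == ncol(counts))
  if (is.null(rownames(counts))) {
    rownames(counts) <- colnames(counts) <- paste0("C", seq_len(nrow(counts)))
  }
  structure(counts, class_sizes = rowSums(counts),
            class = c("confusion_matrix", "matrix"))
}

.cm_check <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion_from_counts(cm)
  if (sum(cm) <= 0) stop("empty confusion matrix")
  cm
}

.prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

#' Per-class (one-vs-rest) classification metrics
#'
#' @param cm a `confusion_matrix` (rows = actual, columns = predicted).
#' @param positive name or index of the positive class.
#' @return List: precision, recall (sensitivity), specificity, f1,
#'   balanced_accuracy. Undefined values are `NA`.
#' @export
per_class_metrics <- function(cm, positive) {
  cm <- .cm_check(cm)
  classes <- rownames(cm)
  i <- if (is.character(positive)) match(positive, classes) else positive
  if (is.na(i)) stop("unknown class: ", positive)
  tp <- cm[i, i]
  fp <- sum(cm[-i, i])
  fn <- sum(cm[i, -i])
  tn <- sum(cm[-i, -i])
  m <- .prf(tp, fp, fn)
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bal <- if (!is.na(m$recall) && !is.na(specificity))
    (m$recall + specificity) / 2 else NA_real_
  list(precision = m$precision, recall = m$recall, specificity = specificity,
       f1 = m$f1, balanced_accuracy = bal)
}

#' Combined-positive classification metrics
#'
#' Micro-averages the one-vs-rest counts over the positive classes
#' (typically the two patient groups): TP is the summed diagonal over the
#' positive classes, FP every erroneous prediction into a positive class
#' (including from the other positive class), FN every positive-class row
#' predicted anywhere other than its own class.
#'
#' @param cm a `confusion_matrix`.
#' @param positives names of the positive classes (strict subset).
#' @return List: precision, recall, f1.
#' @export
combined_positive_metrics <- function(cm, positives = c("EOA", "DCD")) {
  cm <- .cm_check(cm)
  classes <- rownames(cm)
  pos <- match(positives, classes)
  if (anyNA(pos)) stop("unknown positive class")
  if (length(pos) >= length(classes)) stop("positives must be a strict subset")
  tp <- sum(diag(cm)[pos])
  fp <- sum(vapply(pos, function(j) sum(cm[-j, j]), numeric(1)))
  fn <- sum(vapply(pos, function(i) sum(cm[i, -i]), numeric(1)))
  .prf(tp, fp, fn)
}

#' Overall accuracy
#'
#' @param cm a `confusion_matrix`.
#' @return trace(counts) / sum(counts).
#' @export
overall_accuracy <- function(cm) {
  cm <- .cm_check(cm)
  sum(diag(cm)) / sum(cm)
}

# half-up rounding (the tables' display convention); internal values are
# never rounded
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Full metrics report for a confusion matrix
#'
#' Per-class precision, recall, specificity, F1 and balanced accuracy for
#' every class, the combined-positive triple and the overall accuracy.
#'
#' @param cm a `confusion_matrix`.
#' @param positives classes pooled for the combined-positive metrics.
#' @return Object of class `metrics_report`: `$per_class` (data.frame),
#'   `$combined` (list), `$overall_accuracy`.
#' @export
metrics_report <- function(cm, positives = c("EOA", "DCD")) {
  cm <- .cm_check(cm)
  pc <- do.call(rbind, lapply(rownames(cm), function(cl) {
    m <- per_class_metrics(cm, cl)
    data.frame(class = cl, balanced_accuracy = m$balanced_accuracy,
               recall = m$recall, specificity = m$specificity,
               precision = m$precision, f1 = m$f1)
  }))
  structure(list(per_class = pc,
                 combined = combined_positive_metrics(cm, positives),
                 overall_accuracy = overall_accuracy(cm),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat("Overall accuracy:", .round_half_up(x$overall_accuracy, digits), "\n\n")
  df <- x$per_class
  df[, -1] <- lapply(df[, -1], .round_half_up, digits = digits)
  names(df) <- c("Actual", "Balanced Accuracy", "Sensitivity (Recall)",
                 "Specificity", "Precision", "F1-Score")
  print(df, row.names = FALSE)
  cat(sprintf("\nCombined positive (%s): precision %.2f, recall %.2f, F1 %.2f\n",
              "EOA+DCD", x$combined$precision, x$combined$recall, x$combined$f1))
  invisible(x)
}
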