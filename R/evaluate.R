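#' Confusion matrix for multiclass predictions
#'
#' Counts actual-by-predicted pairs: entry `(i, j)` is the number of
#' samples of true class `i` predicted as class `j`. Rows are actual
#' classes, columns predicted, both in the fixed activity encoding order.
#'
#' @param y_true,y_pred equal-length label vectors: integer codes in
#'   `[0, k)`, factors, or characters matching `classes`.
#' @param k number of classes.
#' @param classes class labels used for dimnames (and for decoding
#'   character input).
#' @return a `k x k` integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, k = length(classes),
                      classes = activity_labels()) {
  y_true <- .as_label_codes(y_true, classes[seq_len(k)])
  y_pred <- .as_label_codes(y_pred, classes[seq_len(k)])
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  cm <- table(factor(y_true, levels = 0:(k - 1)),
              factor(y_pred, levels = 0:(k - 1)))
  cm <- matrix(as.integer(cm), k, k,
               dimnames = list(actual = classes[seq_len(k)],
                               predicted = classes[seq_len(k)]))
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' @rdname confusion
#' @param m a bare `k x k` count matrix (rows actual, columns predicted) to
#'   tag as a `confusion_matrix`, e.g. a published matrix being re-analysed.
#' @export
as_confusion <- function(m, classes = activity_labels()) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("entries must be non-negative counts", call. = FALSE)
  }
  k <- nrow(m)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(actual = classes[seq_len(k)],
                      predicted = classes[seq_len(k)])
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' Overall accuracy of a confusion matrix
#'
#' `100 * sum(diagonal) / sum(all entries)`, in percent.
#'
#' @param cm a [confusion()] matrix.
#' @return accuracy in percent (full precision; round for display).
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(unclass(cm))) / tot
}

#' Fall-versus-ADL sensitivity and specificity
#'
#' Collapses the multiclass matrix to binary fall-vs-everything-else and
#' applies the standard definitions: sensitivity `= 100 * TP / (TP + FN)`
#' (true falls detected as falls) and specificity `= 100 * TN / (TN + FP)`
#' (non-fall activities not flagged as falls), where
#' `TP = cm[fall, fall]`, `FN` the rest of the fall row, `FP` the rest of
#' the fall column and `TN` everything else. The result is invariant to
#' permuting the non-fall classes. A zero denominator yields `NaN` with a
#' warning.
#'
#' @param cm a [confusion()] matrix.
#' @param fall_index 1-based row/column of the fall class (default: the
#'   `"falling"` row by name, else the last class).
#' @return named numeric vector `c(sensitivity =, specificity =)` in
#'   percent.
#' @export
fall_binary_metrics <- function(cm, fall_index = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  if (is.null(fall_index)) {
    fall_index <- match("falling", rownames(m))
    if (is.na(fall_index)) fall_index <- nrow(m)
  }
  if (fall_index < 1 || fall_index > nrow(m)) {
    stop("fall_index out of range", call. = FALSE)
  }
  tp <- m[fall_index, fall_index]
  fn <- sum(m[fall_index, ]) - tp
  fp <- sum(m[, fall_index]) - tp
  tn <- sum(m) - tp - fn - fp
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("no fall samples; sensitivity undefined"); NaN
  }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    warning("no non-fall samples; specificity undefined"); NaN
  }
  c(sensitivity = sens, specificity = spec)
}

#' Per-class recall
#'
#' @param cm a [confusion()] matrix.
#' @return named vector of per-class recall in percent (`NaN` for classes
#'   with no samples).
#' @export
per_class_recall <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  100 * diag(m) / rowSums(m)
}

#' Full metrics report
#'
#' Bundles overall accuracy, the fall-vs-ADL binary metrics and per-class
#' recall into one object, exportable as JSON or text.
#'
#' @param cm a [confusion()] matrix.
#' @param fall_index see [fall_binary_metrics()].
#' @return a list of class `metrics_report`.
#' @export
metrics_report <- function(cm, fall_index = NULL) {
  fb <- fall_binary_metrics(cm, fall_index)
  structure(list(accuracy = accuracy(cm),
                 sensitivity = unname(fb["sensitivity"]),
                 specificity = unname(fb["specificity"]),
                 per_class_recall = per_class_recall(cm),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy:    %6.2f %%\n", x$accuracy))
  cat(sprintf("sensitivity: %6.2f %%  (falls detected as falls)\n",
              x$sensitivity))
  cat(sprintf("specificity: %6.2f %%  (ADLs not flagged as falls)\n",
              x$specificity))
  cat("per-class recall (%):\n")
  print(round(x$per_class_recall, 2))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows actual, columns predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Export a metrics report as JSON, and a confusion matrix as CSV
#'
#' @param report a [metrics_report()].
#' @param cm a [confusion()] matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- list(accuracy = report$accuracy, sensitivity = report$sensitivity,
              specificity = report$specificity,
              per_class_recall = as.list(report$per_class_recall))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
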