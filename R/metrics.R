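#' Confusion matrix
#'
#' Tallies true vs predicted labels into a square matrix with rows as the
#' true class and columns as the predicted class, in a fixed label order.
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @param label_order Label order for rows/columns; defaults to the union of
#'   observed labels in first-appearance order (true labels first).
#' @return An object of class `confusion_matrix`: list with `labels` and the
#'   integer `counts` matrix.
#' @export
confusion <- function(true_labels, predicted_labels, label_order = NULL) {
  stopifnot(length(true_labels) == length(predicted_labels))
  if (is.null(label_order)) {
    label_order <- unique(c(true_labels, predicted_labels))
  }
  out <- setdiff(unique(c(true_labels, predicted_labels)), label_order)
  if (length(out) > 0) {
    stop(sprintf("label '%s' is not in label_order", out[1]), call. = FALSE)
  }
  tt <- factor(true_labels, levels = label_order)
  pp <- factor(predicted_labels, levels = label_order)
  counts <- unclass(table(tt, pp))
  dimnames(counts) <- list(true = label_order, predicted = label_order)
  structure(list(labels = label_order, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion matrix> %d classes, %d images\n",
              length(x$labels), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Per-class precision, recall and F1
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2 * precision * recall / (precision + recall). Any 0/0 denominator
#' yields 0 by convention, which deliberately penalizes classes that are
#' never predicted.
#'
#' @param cm A [confusion()] matrix.
#' @param label Class label.
#' @return Named list with `precision`, `recall`, `f1` and `support` (number
#'   of true instances).
#' @export
class_prf <- function(cm, label) {
  stopifnot(inherits(cm, "confusion_matrix"))
  i <- match(label, cm$labels)
  if (is.na(i)) stop(sprintf("label '%s' not in confusion matrix", label), call. = FALSE)
  tp <- cm$counts[i, i]
  fp <- sum(cm$counts[, i]) - tp
  fn <- sum(cm$counts[i, ]) - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, support = tp + fn)
}

#' Full metrics report from a confusion matrix
#'
#' Top-1 accuracy is the trace over the total; macro F1 is the unweighted
#' mean of per-class F1 over the classes actually present in the test set
#' (nonzero support). Classes that are present but never predicted
#' contribute F1 = 0 to the macro mean.
#'
#' @param cm A [confusion()] matrix with at least one tallied image.
#' @return An object of class `metrics_report`: list with `top1_accuracy`,
#'   `per_class` (data frame: label, precision, recall, f1, support) and
#'   `macro_f1`.
#' @export
metrics_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  per <- do.call(rbind, lapply(cm$labels, function(lab) {
    p <- class_prf(cm, lab)
    data.frame(label = lab, precision = p$precision, recall = p$recall,
               f1 = p$f1, support = p$support, stringsAsFactors = FALSE)
  }))
  evaluated <- per$support > 0
  structure(
    list(
      top1_accuracy = sum(diag(cm$counts)) / total,
      per_class = per,
      macro_f1 = mean(per$f1[evaluated]),
      n_images = total
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics> top-1 accuracy %.3f, macro F1 %.3f over %d images\n",
              x$top1_accuracy, x$macro_f1, x$n_images))
  invisible(x)
}

#' Top-1 accuracy of uniform random guessing
#'
#' The chance baseline against which classifier accuracy is judged: a
#' uniform guess over K classes is correct with probability 1/K (about
#' 1.81% for 55 classes).
#'
#' @param n_classes Number of classes K.
#' @return 1 / K.
#' @export
random_chance_accuracy <- function(n_classes) {
  stopifnot(n_classes >= 1)
  1 / n_classes
}

#' Per-class recall table
#'
#' Builds a per-class report in the packaged recall-table dialect: one row
#' per class with its training count, test support and the recall a model
#' achieved - the shape in which per-species results are conventionally
#' reported for camera-trap classifiers.
#'
#' @param cm A [confusion()] matrix from the model's test predictions.
#' @param train_counts Named vector of per-class training-image counts
#'   covering the matrix labels.
#' @param model_name Column name for the recall values.
#' @return A `class_recall_table` data frame (columns `class_label`,
#'   `n_train`, `n_test`, `<model_name>`).
#' @export
per_class_recall_table <- function(cm, train_counts, model_name = "model") {
  stopifnot(inherits(cm, "confusion_matrix"))
  missing_cls <- setdiff(cm$labels, names(train_counts))
  if (length(missing_cls) > 0) {
    stop(sprintf("train_counts missing for class '%s'", missing_cls[1]), call. = FALSE)
  }
  rows <- do.call(rbind, lapply(cm$labels, function(lab) {
    p <- class_prf(cm, lab)
    data.frame(class_label = lab,
               n_train = as.integer(train_counts[[lab]]),
               n_test = as.integer(p$support),
               recall = p$recall, stringsAsFactors = FALSE)
  }))
  names(rows)[names(rows) == "recall"] <- model_name
  structure(rows, models = model_name,
            class = c("class_recall_table", "data.frame"))
}

#' Write a recall table as CSV
#'
#' The written file round-trips through [load_recall_table()].
#'
#' @param tbl A `class_recall_table` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_recall_table <- function(tbl, path) {
  write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}

#' Read a recall table CSV
#'
#' Same dialect as the packaged fixture but without its 55-row integrity
#' requirement; see [load_table1_fixture()].
#'
#' @param path CSV path with columns `class_label`, `n_train`, `n_test` and
#'   one numeric recall column per model.
#' @return A `class_recall_table` data frame.
#' @export
load_recall_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("class_label", "n_train", "n_test")
  for (col in needed) {
    if (!col %in% names(df)) {
      stop(sprintf("recall table is missing required column '%s'", col), call. = FALSE)
    }
  }
  models <- setdiff(names(df), needed)
  for (m in models) df[[m]] <- as.numeric(df[[m]])
  structure(df, models = models, class = c("class_recall_table", "data.frame"))
}
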