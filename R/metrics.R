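#' Multiclass confusion matrix
#'
#' Entry `(i, j)` counts samples whose true class is `i` and predicted class
#' is `j`, in the fixed class order Benign, Malignant, Normal (rows = true,
#' columns = predicted).
#'
#' @param true_labels,predicted_labels character vectors of equal length.
#' @return 3x3 integer matrix with dimnames.
#' @export
confusion <- function(true_labels, predicted_labels) {
  assert_that(length(true_labels) == length(predicted_labels),
              "true and predicted label vectors must have equal length")
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), LUNG_CLASSES)
  assert_that(length(unknown) == 0,
              sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")))
  tf <- factor(true_labels, levels = LUNG_CLASSES)
  pf <- factor(predicted_labels, levels = LUNG_CLASSES)
  cm <- table(tf, pf)
  m <- matrix(as.integer(cm), 3, 3,
              dimnames = list(true = LUNG_CLASSES, predicted = LUNG_CLASSES))
  m
}

assert_cm <- function(cm) {
  assert_that(is.matrix(cm) && all(dim(cm) == c(3, 3)), "confusion matrix must be 3x3")
  assert_that(all(cm >= 0) && all(cm == round(cm)),
              "confusion matrix entries must be non-negative integers")
  invisible(cm)
}

#' One-vs-rest metrics from a confusion matrix
#'
#' For each class: `Tp` (diagonal), `Fp` (column sum minus `Tp`), `Fn` (row
#' sum minus `Tp`), `Tn` (remainder), precision `Tp / (Tp + Fp)`, recall
#' `Tp / (Tp + Fn)`, and their harmonic mean F1. Overall accuracy is
#' `trace / total`. A division by zero yields the metric value 0 with the
#' corresponding `undefined` flag set.
#'
#' @param cm 3x3 confusion matrix (rows = true, columns = predicted).
#' @return a `lungct_metrics` list: `per_class` data.frame (`class`, `Tp`,
#'   `Fp`, `Fn`, `Tn`, `precision`, `recall`, `f1`, `undefined`),
#'   `accuracy`, `total`.
#' @export
compute_metrics <- function(cm) {
  assert_cm(cm)
  total <- sum(cm)
  assert_that(total > 0, "confusion matrix is all zero")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  undefined <- (tp + fp) == 0 | (tp + fn) == 0
  per_class <- data.frame(class = LUNG_CLASSES, Tp = as.integer(tp),
                          Fp = as.integer(fp), Fn = as.integer(fn),
                          Tn = as.integer(tn),
                          precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          undefined = undefined, row.names = NULL)
  res <- list(per_class = per_class,
              accuracy = sum(tp) / total,
              total = as.integer(total))
  class(res) <- "lungct_metrics"
  res
}

#' Class-wise accuracy
#'
#' Per-true-class correct fraction, `cm[i, i] / rowsum(i)`; numerically
#' identical to per-class recall. A zero row sum yields `NA` for that class.
#'
#' @param cm 3x3 confusion matrix.
#' @return named numeric vector over the three classes.
#' @export
classwise_accuracy <- function(cm) {
  assert_cm(cm)
  rs <- rowSums(cm)
  out <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  names(out) <- LUNG_CLASSES
  out
}

fmt_pct <- function(x, digits) {
  ifelse(is.na(x), "n/a", sprintf(paste0("%.", digits, "f%%"), 100 * x))
}

#' Render a metric report
#'
#' Produces a plain-text table and a JSON mirror. Percentages follow the
#' display convention of the pipeline's reports: one decimal place for
#' precision, recall, F1 and overall accuracy; two decimal places for
#' class-wise accuracies. Undefined (division-by-zero) metrics render as
#' `"n/a"` in the text report and `null` in the JSON.
#'
#' @param report a `lungct_metrics` object.
#' @param cm the confusion matrix the report was computed from.
#' @param json_path optional path; when given the JSON mirror is written there.
#' @return list with `text` (character vector of report lines) and `json`
#'   (JSON string).
#' @export
render_report <- function(report, cm, json_path = NULL) {
  assert_that(inherits(report, "lungct_metrics"), "report must be a lungct_metrics")
  assert_cm(cm)
  pc <- report$per_class
  cw <- classwise_accuracy(cm)
  lines <- c("Confusion matrix (rows = true, columns = predicted)",
             sprintf("%-10s %8s %9s %7s", "", "Benign", "Malignant", "Normal"))
  for (i in 1:3) {
    lines <- c(lines, sprintf("%-10s %8d %9d %7d", LUNG_CLASSES[i],
                              cm[i, 1], cm[i, 2], cm[i, 3]))
  }
  lines <- c(lines, "",
             sprintf("%-10s %10s %8s %8s %14s", "Class", "Precision", "Recall",
                     "F1", "Class accuracy"))
  for (i in 1:3) {
    pv <- if (pc$undefined[i]) NA_real_ else pc$precision[i]
    rv <- if (pc$undefined[i]) NA_real_ else pc$recall[i]
    fv <- if (pc$undefined[i]) NA_real_ else pc$f1[i]
    lines <- c(lines, sprintf("%-10s %10s %8s %8s %14s", pc$class[i],
                              fmt_pct(pv, 1), fmt_pct(rv, 1), fmt_pct(fv, 1),
                              fmt_pct(cw[i], 2)))
  }
  lines <- c(lines, "", sprintf("Overall accuracy: %s (%d/%d)",
                                fmt_pct(report$accuracy, 1),
                                sum(diag(cm)), report$total))
  payload <- list(
    confusion = unname(lapply(1:3, function(i) as.integer(cm[i, ]))),
    class_order = LUNG_CLASSES,
    per_class = lapply(1:3, function(i) {
      list(class = pc$class[i],
           Tp = pc$Tp[i], Fp = pc$Fp[i], Fn = pc$Fn[i], Tn = pc$Tn[i],
           precision = if (pc$undefined[i]) NULL else pc$precision[i],
           recall = if (pc$undefined[i]) NULL else pc$recall[i],
           f1 = if (pc$undefined[i]) NULL else pc$f1[i],
           class_accuracy = if (is.na(cw[i])) NULL else unname(cw[i]))
    }),
    overall_accuracy = report$accuracy,
    total = report$total)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(json_path)) writeLines(json, json_path)
  list(text = lines, json = as.character(json))
}
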