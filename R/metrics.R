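#' Confusion matrix over a scheme's target classes
#'
#' @param truth,predicted Character vectors of target class labels, equal
#'   length.
#' @param classes Character vector fixing the axis order (e.g.
#'   `class_scheme("three")$target_order`).
#' @return Integer K-by-K matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes) {
  if (length(truth) != length(predicted))
    stop("truth and predicted have different lengths (",
         length(truth), " vs ", length(predicted), ")")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0)
    stop("label(s) outside the scheme: ", paste(bad, collapse = ", "))
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' One-vs-rest confusion counts per class
#'
#' For each class, TP is its diagonal entry, FP its column sum minus TP,
#' FN its row sum minus TP, and TN the remainder; TP+FP+TN+FN equals the
#' sample count for every class.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return data.frame with columns `class`, `TP`, `FP`, `FN`, `TN`,
#'   `support` (row sum).
#' @export
ovr_counts <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  data.frame(class = rownames(cm), TP = as.integer(tp), FP = as.integer(fp),
             FN = as.integer(fn), TN = as.integer(n - tp - fp - fn),
             support = as.integer(rowSums(cm)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' The five evaluation metrics from one-vs-rest counts
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN); F1 = harmonic mean of
#' precision and recall; accuracy = (TP+TN)/(TP+FP+TN+FN); specificity =
#' TN/(TN+FP). A metric whose denominator is zero is defined as 0, with a
#' warning -- a class never predicted gets precision 0, not NaN.
#'
#' @param counts A one-row slice of [ovr_counts()], or any list with
#'   numeric `TP`, `FP`, `FN`, `TN`.
#' @return Named numeric vector: `precision`, `recall`, `f1`, `accuracy`,
#'   `specificity`, all in \[0,1\].
#' @export
score_counts <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator in ", what, "; defining it as 0")
      return(0)
    }
    num / den
  }
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  acc <- safe_div(tp + tn, tp + fp + tn + fn, "accuracy")
  spec <- safe_div(tn, tn + fp, "specificity")
  c(precision = prec, recall = rec, f1 = f1, accuracy = acc,
    specificity = spec)
}

#' Full classification report for one prediction set
#'
#' Computes the K-by-K confusion matrix, per-class one-vs-rest counts and
#' metrics, and three aggregates: `macro` (unweighted mean over classes,
#' the default headline), `weighted` (support-weighted mean), and `micro`
#' (metrics of the summed one-vs-rest counts; for single-label problems
#' micro precision = micro recall = overall accuracy).
#'
#' @param truth,predicted Character vectors of target class labels.
#' @param scheme A [class_scheme()], or a character vector of class names.
#' @param model_name Optional name recorded in the report.
#' @return An object of class `cyto_report`: list with `confusion`,
#'   `per_class` (data.frame), `macro`, `weighted`, `micro` (named
#'   5-vectors), `classes`, `model_name`.
#' @export
classification_report <- function(truth, predicted, scheme,
                                  model_name = NULL) {
  classes <- if (inherits(scheme, "class_scheme")) scheme$target_order
             else as.character(scheme)
  cm <- confusion_matrix(truth, predicted, classes)
  cnt <- ovr_counts(cm)
  per <- do.call(rbind, lapply(seq_len(nrow(cnt)), function(i)
    as.data.frame(as.list(suppressWarnings(score_counts(cnt[i, ]))))))
  per <- cbind(cnt, per)
  metric_cols <- c("precision", "recall", "f1", "accuracy", "specificity")
  macro <- colMeans(per[, metric_cols])
  wts <- per$support / sum(per$support)
  weighted <- colSums(per[, metric_cols] * wts)
  micro <- suppressWarnings(score_counts(list(
    TP = sum(cnt$TP), FP = sum(cnt$FP), FN = sum(cnt$FN), TN = sum(cnt$TN))))
  structure(list(confusion = cm, per_class = per,
                 macro = stats::setNames(as.numeric(macro), metric_cols),
                 weighted = stats::setNames(as.numeric(weighted), metric_cols),
                 micro = micro, classes = classes,
                 model_name = model_name %||% "model"),
            class = "cyto_report")
}

#' @export
print.cyto_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cyto_report> %s (%d samples, %d classes)\n",
              x$model_name, sum(x$confusion), length(x$classes)))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  cat("per-class:\n")
  print(cbind(x$per_class[, c("class", "support")],
              round(x$per_class[, c("precision", "recall", "f1", "accuracy",
                                    "specificity")], digits)),
        row.names = FALSE)
  cat("macro   :", paste(sprintf("%s=%.*f", names(x$macro), digits, x$macro),
                         collapse = " "), "\n")
  cat("micro   :", paste(sprintf("%s=%.*f", names(x$micro), digits, x$micro),
                         collapse = " "), "\n")
  invisible(x)
}

#' Write a classification report to JSON
#'
#' @param report A `cyto_report`.
#' @param path Output path.
#' @param extra Optional named list merged into the JSON (e.g. seeds).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, extra = NULL) {
  obj <- c(list(model_name = report$model_name, classes = report$classes,
                confusion = unclass(report$confusion),
                per_class = report$per_class,
                macro = as.list(report$macro),
                weighted = as.list(report$weighted),
                micro = as.list(report$micro)),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
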