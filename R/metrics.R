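#' Three-class confusion matrix
#'
#' Rows are true classes, columns predicted classes, in class level
#' order. Per-class TP/FP/FN/TN counts follow the one-vs-rest reading:
#' TP_i is the diagonal cell, FP_i the rest of column i, FN_i the rest of
#' row i, and TN_i the remainder, so TP_i + FP_i + FN_i + TN_i equals the
#' sample count for every class.
#'
#' @param y_true,y_pred factors (or vectors coercible to factors over the
#'   union of their values) of equal, nonzero length
#' @return A `confusion_matrix`: the counts matrix with per-class
#'   `tp`, `fp`, `fn`, `tn` attached as attributes.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  lev <- levels(as.factor(y_true))
  lev <- union(lev, levels(as.factor(y_pred)))
  y_true <- factor(y_true, levels = lev)
  y_pred <- factor(y_pred, levels = lev)
  cm <- table(true = y_true, pred = y_pred)
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm),
              dimnames = list(true = lev, pred = lev))
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- sum(m) - tp - fp - fn
  structure(m, class = c("confusion_matrix", "matrix"),
            tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Macro-averaged classification metrics
#'
#' Accuracy is total TP over total (TP + FP), which for a square
#' confusion matrix equals trace over total. Macro precision and recall
#' are unweighted means of the per-class ratios; a class with a zero
#' denominator contributes 0 (with a warning). Macro-F1 is the harmonic
#' mean of macro precision and macro recall.
#'
#' @param cm a `confusion_matrix` from [confusion()]
#' @return A `metric_report` list: `ACC`, `macro_P`, `macro_R`,
#'   `macro_F1`, `per_class` (precision/recall per class) and
#'   `confusion`.
#' @export
macro_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- attr(cm, "tp"); fp <- attr(cm, "fp"); fn <- attr(cm, "fn")
  acc <- sum(tp) / sum(tp + fp)
  prec <- numeric(length(tp)); rec <- numeric(length(tp))
  for (i in seq_along(tp)) {
    if (tp[i] + fp[i] == 0) {
      warning("class ", names(tp)[i], " never predicted; precision set to 0")
      prec[i] <- 0
    } else prec[i] <- tp[i] / (tp[i] + fp[i])
    if (tp[i] + fn[i] == 0) {
      warning("class ", names(tp)[i], " absent from truth; recall set to 0")
      rec[i] <- 0
    } else rec[i] <- tp[i] / (tp[i] + fn[i])
  }
  mp <- mean(prec); mr <- mean(rec)
  f1 <- if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr)
  structure(
    list(ACC = acc, macro_P = mp, macro_R = mr, macro_F1 = f1,
         per_class = data.frame(class = names(tp), precision = prec,
                                recall = rec, row.names = NULL),
         confusion = unclass(cm)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> ACC %.4f | macro-P %.4f | macro-R %.4f | macro-F1 %.4f",
              x$ACC, x$macro_P, x$macro_R, x$macro_F1))
  if (!is.null(x$macro_AUC)) cat(sprintf(" | macro-AUC %.4f", x$macro_AUC))
  cat("\n")
  invisible(x)
}

#' One-vs-rest ROC curve for a single class
#'
#' Sweeps thresholds over the distinct scores of the class's probability
#' column (plus infinite endpoints); at each threshold a sample is called
#' positive when its score is >= the threshold. Ties therefore move in
#' groups, which makes the trapezoid AUC equal to the Mann-Whitney
#' statistic with 1/2 credit per tie.
#'
#' @param y_true factor of true labels
#' @param probs row-stochastic matrix with one column per class
#' @param class_i class name or column index
#' @return data.frame of ROC points (`threshold`, `fpr`, `tpr`),
#'   from (0,0) to (1,1).
#' @export
roc_ovr <- function(y_true, probs, class_i) {
  probs <- as.matrix(probs)
  cl <- if (is.numeric(class_i)) colnames(probs)[class_i] else class_i
  y <- as.factor(y_true)
  pos <- y == cl
  if (!any(pos)) stop("class ", cl, " absent from y_true; AUC undefined")
  if (all(pos)) stop("class ", cl, " has no negatives; AUC undefined")
  s <- probs[, cl]
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  pts <- vapply(thr, function(th) {
    call_pos <- s >= th
    c(fpr = sum(call_pos & !pos) / sum(!pos),
      tpr = sum(call_pos & pos) / sum(pos))
  }, numeric(2))
  data.frame(threshold = thr, fpr = pts["fpr", ], tpr = pts["tpr", ])
}

.auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Macro-averaged one-vs-rest AUC
#'
#' Unweighted mean over classes of the one-vs-rest trapezoid AUC of each
#' class's probability column. By default a class absent from `y_true`
#' raises an error; with `skip_missing = TRUE` the mean runs over the
#' defined classes only.
#'
#' @inheritParams roc_ovr
#' @param skip_missing average over present classes only (default FALSE)
#' @return Scalar macro-AUC in \[0, 1\].
#' @export
macro_auc <- function(y_true, probs, skip_missing = FALSE) {
  probs <- as.matrix(probs)
  classes <- colnames(probs)
  present <- classes %in% as.character(y_true)
  if (!skip_missing && !all(present)) {
    stop("class ", classes[!present][1],
         " absent from y_true; AUC undefined (set skip_missing = TRUE to average over present classes)")
  }
  aucs <- vapply(classes[present], function(cl) {
    .auc_trapezoid(roc_ovr(y_true, probs, cl))
  }, numeric(1))
  mean(aucs)
}

#' Full evaluation of probabilistic three-class predictions
#'
#' Convenience wrapper: argmax labels, confusion matrix, macro metrics
#' and macro-AUC in one `metric_report`.
#'
#' @param y_true factor of true labels
#' @param probs row-stochastic probability matrix with class columns
#' @return A `metric_report` with `macro_AUC` and `per_class_auc` filled
#'   in.
#' @export
evaluate_predictions <- function(y_true, probs) {
  probs <- as.matrix(probs)
  y <- as.factor(y_true)
  pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                 levels = levels(y))
  rep <- macro_metrics(confusion(y, pred))
  rep$macro_AUC <- macro_auc(y, probs)
  rep$per_class_auc <- vapply(colnames(probs), function(cl) {
    .auc_trapezoid(roc_ovr(y, probs, cl))
  }, numeric(1))
  rep
}

#' Serialize a metric report to JSON
#' @param report a `metric_report`
#' @param path output path
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  jsonlite::write_json(
    list(ACC = report$ACC, macro_P = report$macro_P, macro_R = report$macro_R,
         macro_F1 = report$macro_F1, macro_AUC = report$macro_AUC,
         per_class_auc = as.list(report$per_class_auc),
         confusion = report$confusion),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
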