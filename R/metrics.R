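# Evaluation metrics: confusion matrix, per-class one-vs-rest metrics,
# multi-class balanced accuracy (two published definitions), ROC/AUC,
# Bland-Altman limits of agreement.

#' Confusion matrix over the three phases
#'
#' Rows are the true class, columns the predicted class, in the order
#' exhalation, inhalation, nonbreathing.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return 3x3 integer matrix.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("confusion: length mismatch between truth and predictions",
         call. = FALSE)
  }
  tab <- table(factor(as.character(y_true), levels = PHASES),
               factor(as.character(y_pred), levels = PHASES))
  m <- matrix(as.integer(tab), nrow = N_CLASSES,
              dimnames = list(true = PHASES, predicted = PHASES))
  m
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class: precision = TP/(TP+FP), recall/sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), F1 = 2PR/(P+R), balanced
#' accuracy = (recall + specificity)/2, plus macro averages of every
#' column. Ratios with a zero denominator are reported as `NaN` with a
#' warning, never silently as 0.
#'
#' @param cm a 3x3 confusion matrix from [confusion()].
#' @return data.frame with one row per class plus a `macro` row.
#' @export
per_class_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("per_class_metrics: empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warning(sprintf("%s undefined for class '%s' (zero denominator)",
                      what, cl), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  rows <- lapply(seq_len(N_CLASSES), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    cl <- PHASES[i]
    precision <- safe_div(tp, tp + fp, "precision", cl)
    recall <- safe_div(tp, tp + fn, "recall", cl)
    specificity <- safe_div(tn, tn + fp, "specificity", cl)
    f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
      NaN
    } else 2 * precision * recall / (precision + recall)
    data.frame(class = cl, precision = precision, recall = recall,
               specificity = specificity, f1 = f1,
               balanced_accuracy = (recall + specificity) / 2)
  })
  out <- do.call(rbind, rows)
  macro <- data.frame(class = "macro",
                      precision = mean(out$precision),
                      recall = mean(out$recall),
                      specificity = mean(out$specificity),
                      f1 = mean(out$f1),
                      balanced_accuracy = mean(out$balanced_accuracy))
  rbind(out, macro)
}

#' Multi-class balanced accuracy
#'
#' Two published aggregates: `kelleher` is the mean of the per-class
#' recalls; `urbanowicz` is the mean of the per-class balanced
#' accuracies (each the mean of that class's sensitivity and
#' specificity).
#'
#' @param report output of [per_class_metrics()], or a data.frame with
#'   `class`, `recall` and `balanced_accuracy` columns.
#' @param mode `"kelleher"` or `"urbanowicz"`.
#' @return Single numeric value.
#' @export
multiclass_balanced_accuracy <- function(report,
                                         mode = c("kelleher", "urbanowicz")) {
  mode <- match.arg(mode)
  per <- report[report$class %in% PHASES, , drop = FALSE]
  vals <- if (mode == "kelleher") per$recall else per$balanced_accuracy
  bad <- is.na(vals) | is.nan(vals)
  if (any(bad)) {
    stop(sprintf("multiclass_balanced_accuracy: undefined component for class %s",
                 paste(per$class[bad], collapse = ", ")), call. = FALSE)
  }
  mean(vals)
}

#' Balanced accuracy from sensitivity and specificity
#'
#' The per-class definition: the mean of recall/sensitivity and
#' specificity. Vectorised.
#'
#' @param recall,specificity values in `[0, 1]`.
#' @return `(recall + specificity) / 2`.
#' @export
balanced_accuracy <- function(recall, specificity) (recall + specificity) / 2

#' F1 score from precision and recall
#' @param precision,recall values in `[0, 1]`.
#' @return Harmonic mean `2PR/(P+R)`.
#' @export
f1_score <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' One-vs-rest ROC curve and AUC
#'
#' Threshold sweep over the sorted unique scores (rule `score >= tau ->
#' positive`); AUC by the trapezoidal rule. With ties this equals the
#' tie-corrected Mann-Whitney statistic.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical/0-1 positives; both classes required.
#' @return List with `points` (data.frame fpr, tpr, from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (all(labels) || !any(labels)) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  taus <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  tpr <- c(0, vapply(taus, function(tau) sum(scores >= tau & labels) / n_pos,
                     numeric(1)))
  fpr <- c(0, vapply(taus, function(tau) sum(scores >= tau & !labels) / n_neg,
                     numeric(1)))
  if (tpr[length(tpr)] != 1 || fpr[length(fpr)] != 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  }
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = x - y`, their mean and sample SD (n - 1), and the
#' limits of agreement `mean(d) +/- 1.96 * sd(d)`.
#'
#' @param x,y equal-length paired measurements, n >= 2.
#' @return List with `differences`, `means` (pair means, for plotting),
#'   `mean_diff`, `sd_diff`, `lower_limit`, `upper_limit`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("bland_altman: need at least 2 pairs", call. = FALSE)
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  list(differences = d, means = (x + y) / 2, mean_diff = m, sd_diff = s,
       lower_limit = m - 1.96 * s, upper_limit = m + 1.96 * s)
}
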