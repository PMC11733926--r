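# Evaluation metrics for regression (MAE, MSE, RMSE, Pearson R, R^2) and
# binary classification (accuracy, precision, recall, F1, AUC-ROC).

.check_pair <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  invisible(TRUE)
}

#' Regression error metrics
#'
#' \code{mae} is the mean absolute error, \code{mse} the mean squared
#' error and \code{rmse} its square root.
#'
#' @param y_true numeric vector of true values.
#' @param y_pred numeric vector of predictions.
#' @return a single nonnegative number.
#' @export
mae <- function(y_true, y_pred) {
  .check_pair(y_true, y_pred)
  mean(abs(y_true - y_pred))
}

#' @rdname mae
#' @export
mse <- function(y_true, y_pred) {
  .check_pair(y_true, y_pred)
  mean((y_true - y_pred)^2)
}

#' @rdname mae
#' @export
rmse <- function(y_true, y_pred) sqrt(mse(y_true, y_pred))

#' Pearson correlation and coefficient of determination
#'
#' \code{pearson_r} is the Pearson correlation coefficient
#' cov(y, yhat) / (sd(y) sd(yhat)) (population 1/N convention; the ratio is
#' identical under the sample convention). \code{r_squared} is its square.
#'
#' @inheritParams mae
#' @return \code{pearson_r}: a number in [-1, 1]; \code{r_squared}: in [0, 1].
#' @export
pearson_r <- function(y_true, y_pred) {
  .check_pair(y_true, y_pred)
  sy <- stats::sd(y_true); sp <- stats::sd(y_pred)
  if (!is.finite(sy) || !is.finite(sp) || sy == 0 || sp == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  mean((y_true - mean(y_true)) * (y_pred - mean(y_pred))) /
    sqrt(mean((y_true - mean(y_true))^2) * mean((y_pred - mean(y_pred))^2))
}

#' @rdname pearson_r
#' @export
r_squared <- function(y_true, y_pred) pearson_r(y_true, y_pred)^2

#' Confusion counts from labels and predicted classes
#'
#' @param y_true 0/1 labels.
#' @param y_class 0/1 predicted classes.
#' @return list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(y_true, y_class) {
  .check_pair(y_true, y_class)
  stopifnot(all(y_true %in% c(0, 1)), all(y_class %in% c(0, 1)))
  list(TP = sum(y_true == 1 & y_class == 1),
       TN = sum(y_true == 0 & y_class == 0),
       FP = sum(y_true == 0 & y_class == 1),
       FN = sum(y_true == 1 & y_class == 0))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 (the harmonic mean of precision and
#' recall). Degenerate 0/0 ratios are reported as 0 and flagged in the
#' \code{degenerate} field rather than raising an error.
#'
#' @param counts list with TP, TN, FP, FN (see \code{\link{confusion_counts}}).
#' @return list with accuracy, precision, recall, f1 and a character vector
#'   \code{degenerate} naming any 0/0 metrics.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  stopifnot(n >= 1)
  degenerate <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); return(0) }
    num / den
  }
  precision <- ratio(TP, TP + FP, "precision")
  recall <- ratio(TP, TP + FN, "recall")
  f1 <- ratio(2 * precision * recall, precision + recall, "f1")
  list(accuracy = (TP + TN) / n, precision = precision, recall = recall,
       f1 = f1, degenerate = degenerate)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive is scored above a random negative, with ties counted 1/2.
#' Invariant under strictly increasing transforms of the scores.
#'
#' @param y_true 0/1 labels (both classes must be present).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(y_true, scores) {
  .check_pair(y_true, scores)
  stopifnot(all(y_true %in% c(0, 1)))
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("undefined AUC: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Metrics report for a prediction set
#'
#' Convenience wrapper computing the task-appropriate metric set; for
#' multi-task classification tables, metrics are averaged (unweighted) over
#' tasks with molecules missing a task's label skipped per task.
#'
#' @param y_true numeric vector or matrix (one column per task).
#' @param y_pred matching vector/matrix of predictions (probabilities for
#'   classification).
#' @param task_type "regression" or "classification".
#' @param threshold class-decision threshold for classification (default 0.5).
#' @return list of metrics; for multi-task input also \code{per_task}.
#' @export
metrics_report <- function(y_true, y_pred,
                           task_type = c("regression", "classification"),
                           threshold = 0.5) {
  task_type <- match.arg(task_type)
  if (is.matrix(y_true) && ncol(y_true) > 1) {
    per <- lapply(seq_len(ncol(y_true)), function(j) {
      keep <- !is.na(y_true[, j])
      metrics_report(y_true[keep, j], y_pred[keep, j], task_type, threshold)
    })
    names(per) <- colnames(y_true)
    num <- names(per[[1]])[vapply(per[[1]], is.numeric, logical(1))]
    avg <- lapply(num, function(nm) {
      mean(vapply(per, function(p) p[[nm]], numeric(1)))
    })
    names(avg) <- num
    return(c(avg, list(per_task = per)))
  }
  y_true <- as.vector(y_true); y_pred <- as.vector(y_pred)
  keep <- !is.na(y_true)
  y_true <- y_true[keep]; y_pred <- y_pred[keep]
  if (task_type == "regression") {
    list(mae = mae(y_true, y_pred), mse = mse(y_true, y_pred),
         rmse = rmse(y_true, y_pred),
         r = pearson_r(y_true, y_pred), r2 = r_squared(y_true, y_pred),
         n = length(y_true))
  } else {
    cm <- classification_metrics(
      confusion_counts(y_true, as.numeric(y_pred >= threshold)))
    list(auc = auc_roc(y_true, y_pred), accuracy = cm$accuracy,
         precision = cm$precision, recall = cm$recall, f1 = cm$f1,
         n = length(y_true))
  }
}
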