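#' Classification report
#'
#' Light container for predictions on a target sample: predicted 0/1
#' labels, suspicion-increasing composite scores with their threshold,
#' and optional posterior probabilities / estimated contamination.
#' Confusion counts and rates are attached by [confusion_metrics()]
#' once ground truth is available.
#'
#' @param predicted integer vector of 0/1 predictions.
#' @param scores numeric composite scores (suspicion-increasing).
#' @param threshold scalar threshold applied to `scores`.
#' @param posterior optional posterior P(bot) per row.
#' @param lambda_hat optional estimated contamination rate.
#' @return object of class `classification_report`.
#' @export
classification_report <- function(predicted, scores = NULL, threshold = NA_real_,
                                  posterior = NULL, lambda_hat = NULL) {
  predicted <- as.integer(predicted)
  stopifnot(all(predicted %in% c(0L, 1L)))
  structure(list(predicted = predicted, scores = scores,
                 threshold = threshold, posterior = posterior,
                 lambda_hat = lambda_hat,
                 flag_rate = mean(predicted)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n = %d, flagged %d (flag rate %.3f)%s\n",
              length(x$predicted), sum(x$predicted), x$flag_rate,
              if (!is.null(x$lambda_hat))
                sprintf(", lambda_hat = %.3f", x$lambda_hat) else ""))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  accuracy %.3f | specificity %s | sensitivity %s\n",
                m$accuracy,
                ifelse(is.na(m$specificity), "NA", sprintf("%.3f", m$specificity)),
                ifelse(is.na(m$sensitivity), "NA", sprintf("%.3f", m$sensitivity))))
  }
  invisible(x)
}

#' Confusion counts and derived rates
#'
#' Convention: class 1 = bot = positive. Flagging a bot is a true
#' positive; sparing a human is a true negative. Accuracy =
#' (TP+TN)/n, specificity = TN/(TN+FP), sensitivity = TP/(TP+FN),
#' flag rate = (TP+FP)/n. A rate whose class is absent is `NA` and
#' noted in `undefined`.
#'
#' @param truth true 0/1 labels.
#' @param predicted predicted 0/1 labels, or a [classification_report].
#' @return a [classification_report] with a `metrics` field: `tp`,
#'   `fp`, `tn`, `fn`, `accuracy`, `specificity`, `sensitivity`,
#'   `flag_rate`, `undefined`.
#' @export
confusion_metrics <- function(truth, predicted) {
  report <- NULL
  if (inherits(predicted, "classification_report")) {
    report <- predicted
    predicted <- report$predicted
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  stopifnot(all(truth %in% 0:1), all(predicted %in% 0:1))
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fn <- sum(truth == 1L & predicted == 0L)
  n <- length(truth)
  metrics <- list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    accuracy = (tp + tn) / n,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    flag_rate = (tp + fp) / n,
    undefined = c(if (tn + fp == 0) "specificity",
                  if (tp + fn == 0) "sensitivity"))
  if (is.null(report)) report <- classification_report(predicted)
  report$metrics <- metrics
  report
}

#' Accuracy as a contamination-weighted mean of sensitivity and specificity
#'
#' `accuracy = lambda * sensitivity + (1 - lambda) * specificity`: at a
#' given operating point, overall accuracy is the mean of the two
#' conditional rates weighted by the bot prevalence. This identity is
#' exact for fixed class counts and is the lens through which
#' specificity-calibrated cutoffs lose accuracy at high contamination.
#'
#' @param lambda contamination rate in `[0, 1]`.
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @return the accuracy, in `[0, 1]`.
#' @examples
#' weighted_accuracy(0.30, sensitivity = 0.80, specificity = 0.96)  # 0.912
#' @export
weighted_accuracy <- function(lambda, sensitivity, specificity) {
  if (any(c(lambda, sensitivity, specificity) < 0) ||
      any(c(lambda, sensitivity, specificity) > 1))
    stop("all arguments must lie in [0, 1]")
  lambda * sensitivity + (1 - lambda) * specificity
}

#' Empirical AUC (rank-sum formulation)
#'
#' Probability that a randomly chosen bot outscores a randomly chosen
#' human on a suspicion-increasing score, with ties counted 1/2 —
#' equivalently the normalized Wilcoxon rank-sum statistic.
#'
#' @param scores suspicion-increasing numeric scores.
#' @param truth 0/1 labels (1 = bot).
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% 0:1))
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("empirical AUC needs both classes present")
  r <- rank(scores)                      # midranks handle ties
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
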