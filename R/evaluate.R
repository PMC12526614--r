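# Confusion counts, classification metrics, ROC/AUC, and the feature-set
# comparison report.  The positive class is KI (label 1) throughout.

#' Confusion counts
#'
#' @param true,pred Binary label vectors (1 = KI positive class).
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`, `n`.
#' @export
confusion <- function(true, pred) {
  abort_if(length(true) != length(pred),
           "confusion: label vectors differ in length")
  structure(list(
    TP = sum(true == 1 & pred == 1),
    FP = sum(true == 0 & pred == 1),
    TN = sum(true == 0 & pred == 0),
    FN = sum(true == 1 & pred == 0),
    n = length(true)
  ), class = "confusion_counts")
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)` (binary, per-positive-class), `accuracy = (TP+TN)/n`
#' in percent.  Zero denominators yield 0 with a warning.
#'
#' @param c A `confusion_counts` (or list with TP/FP/TN/FN).
#' @return List with `precision`, `recall`, `f1`, `accuracy_pct`.
#' @export
classification_metrics <- function(c) {
  n <- c$TP + c$FP + c$TN + c$FN
  abort_if(n == 0, "classification_metrics: no evaluated samples")
  precision <- if (c$TP + c$FP == 0) {
    warning("precision undefined (no positive predictions); reported as 0",
            call. = FALSE)
    0
  } else c$TP / (c$TP + c$FP)
  recall <- if (c$TP + c$FN == 0) {
    warning("recall undefined (no positive cases); reported as 0", call. = FALSE)
    0
  } else c$TP / (c$TP + c$FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       accuracy_pct = 100 * (c$TP + c$TN) / n)
}

#' F1 score from precision and recall
#'
#' @param precision,recall Metric values in `[0, 1]`.
#' @return `2PR/(P+R)` (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all distinct score thresholds (ties grouped) and integrates by the
#' trapezoidal rule, which equals the probability that a random positive
#' outscores a random negative with ties counted one half (Mann-Whitney).
#'
#' @param scores Numeric classifier scores (higher = more KI-like).
#' @param true Binary labels with both classes present.
#' @return List with `roc` (data frame `fpr,tpr,threshold`) and `auc`.
#' @export
roc_auc <- function(scores, true) {
  abort_if(length(unique(true)) < 2, "roc_auc: single-class labels")
  th <- sort(unique(scores), decreasing = TRUE)
  np <- sum(true == 1); nn <- sum(true == 0)
  tpr <- vapply(th, function(s) sum(scores >= s & true == 1) / np, 0)
  fpr <- vapply(th, function(s) sum(scores >= s & true == 0) / nn, 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, th))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Accuracy of the majority-class predictor
#'
#' The floor any useful classifier must beat on imbalanced data.
#'
#' @param labels Binary label vector.
#' @return Accuracy in percent, `max(class fraction) * 100`.
#' @export
majority_baseline <- function(labels) {
  100 * max(table(labels)) / length(labels)
}

# Stratified train/test split indices, deterministic for a seed.
stratified_split <- function(labels, fraction, seed) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      take <- max(1, round(fraction * length(idx)))
      train <- c(train, idx[sample.int(length(idx), take)])
    }
    sort(train)
  })
}

subset_dataset <- function(dataset, idx) {
  dataset$x <- dataset$x[idx, , , drop = FALSE]
  for (nm in c("labels", "subject", "squat", "ks_stat")) {
    dataset[[nm]] <- dataset[[nm]][idx]
  }
  dataset$summaries <- dataset$summaries[idx, , drop = FALSE]
  if (!is.null(dataset$truth)) dataset$truth <- dataset$truth[idx]
  dataset
}

#' Compare classifiers across feature sets
#'
#' For each (model, feature set) pair: stratified split by the configured
#' seed, train on the training portion, predict the held-out portion, and
#' emit one report row with AUC, recall, F1, precision and accuracy.
#'
#' @param dataset A full `labeled_dataset` with both classes.
#' @param sets Named list of feature-id vectors
#'   (default [default_feature_sets()]).
#' @param models Character subset of `c("lstm", "svm")`.
#' @param cfg A [train_config()].
#' @return A `metrics_report` data frame: `model, feature_sets, auc, recall,
#'   f1, precision, accuracy_pct`, plus attributes `split` and `seed`.
#' @export
compare_feature_sets <- function(dataset, sets = default_feature_sets(),
                                 models = c("lstm", "svm"),
                                 cfg = train_config()) {
  abort_if(length(unique(dataset$labels)) < 2,
           "compare_feature_sets: dataset has a single class")
  train_idx <- stratified_split(dataset$labels, cfg$split, cfg$seed)
  test_idx <- setdiff(seq_along(dataset$labels), train_idx)
  rows <- list()
  for (model in models) {
    for (si in seq_along(sets)) {
      ds <- make_set(dataset, sets[[si]])
      tr <- subset_dataset(ds, train_idx)
      te <- subset_dataset(ds, test_idx)
      fit <- if (model == "lstm") train_lstm(tr, cfg) else train_svm(tr, cfg)
      pr <- stats::predict(fit, te)
      m <- classification_metrics(confusion(te$labels, pr$label))
      auc <- roc_auc(pr$score, te$labels)$auc
      rows[[length(rows) + 1L]] <- data.frame(
        model = model,
        feature_sets = names(sets)[si] %||% paste(sets[[si]], collapse = ","),
        auc = auc, recall = m$recall, f1 = m$f1, precision = m$precision,
        accuracy_pct = m$accuracy_pct)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "split") <- sprintf("stratified holdout %.0f/%.0f",
                                100 * cfg$split, 100 * (1 - cfg$split))
  attr(out, "seed") <- cfg$seed
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Format a metrics report as an aligned text table
#'
#' Metrics rounded to 2 decimal places, matching the benchmark table layout.
#'
#' @param report A `metrics_report`.
#' @return Character vector of table lines, invisibly; printed as a side
#'   effect.
#' @export
format_report <- function(report) {
  df <- as.data.frame(report)
  for (nm in c("auc", "recall", "f1", "precision", "accuracy_pct")) {
    df[[nm]] <- sprintf("%.2f", df[[nm]])
  }
  lines <- utils::capture.output(print(df, row.names = FALSE))
  cat(lines, sep = "\n")
  invisible(lines)
}
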