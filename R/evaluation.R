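#' Confusion matrix with PAF as the positive class
#'
#' @param truth,pred Label vectors with values in `{PAF, normal}`.
#' @return A list of class `confusion_matrix` with counts `TP`, `FN`,
#'   `TN`, `FP`.
#' @export
confusion_matrix <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) == 0L || length(truth) != length(pred))
    stopf("'truth' and 'pred' must be non-empty and the same length")
  structure(list(TP = sum(truth == "PAF" & pred == "PAF"),
                 FN = sum(truth == "PAF" & pred == "normal"),
                 TN = sum(truth == "normal" & pred == "normal"),
                 FP = sum(truth == "normal" & pred == "PAF")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("PAF", "normal"),
                              predicted = c("PAF", "normal")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall on PAF), specificity, positive and
#' negative predictive values, and the F1 score under both class
#' conventions: `F1_positive` is the harmonic mean of PPV and
#' sensitivity, `F1_negative` of NPV and specificity. Any metric with a
#' zero denominator is reported missing.
#'
#' @param cm A [confusion_matrix()], or `TP` as a count when the counts
#'   are given directly.
#' @param FN,TN,FP Counts when not passing a `confusion_matrix`.
#' @return Named list of proportions.
#' @examples
#' confusion_metrics(confusion_matrix(rep(c("PAF", "normal"), c(2, 2)),
#'                                    c("PAF", "PAF", "normal", "normal")))
#' @export
confusion_metrics <- function(cm, FN = NULL, TN = NULL, FP = NULL) {
  if (!inherits(cm, "confusion_matrix"))
    cm <- structure(list(TP = cm, FN = FN, TN = TN, FP = FP),
                    class = "confusion_matrix")
  tot <- cm$TP + cm$FN + cm$TN + cm$FP
  if (tot == 0L) stopf("domain error: empty confusion matrix")
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- frac(cm$TP, cm$TP + cm$FN)
  spec <- frac(cm$TN, cm$TN + cm$FP)
  ppv <- frac(cm$TP, cm$TP + cm$FP)
  npv <- frac(cm$TN, cm$TN + cm$FN)
  hm <- function(a, b) if (is.na(a) || is.na(b) || a + b == 0)
    NA_real_ else 2 * a * b / (a + b)
  list(accuracy = (cm$TP + cm$TN) / tot,
       sensitivity = sens, specificity = spec,
       PPV = ppv, NPV = npv,
       F1_positive = hm(ppv, sens),
       F1_negative = hm(npv, spec))
}

#' Area under the ROC curve
#'
#' Mann–Whitney U statistic normalized: the probability that a random
#' PAF score exceeds a random normal score, with ties given half
#' credit; equivalent to trapezoidal integration of the ROC curve over
#' all thresholds.
#'
#' @param scores Numeric classifier scores (larger = more PAF-like).
#' @param labels Labels in `{PAF, normal}`; both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "PAF"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stopf("domain error: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams auroc
#' @return Data frame of `(FPR, TPR)` over all score thresholds.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.character(labels)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == "PAF")
  fp <- cumsum(labels[o] == "normal")
  keep <- !duplicated(scores[o][length(o):1])[length(o):1] |
    seq_along(o) == length(o)
  data.frame(FPR = c(0, fp[keep] / max(1, sum(labels == "normal"))),
             TPR = c(0, tp[keep] / max(1, sum(labels == "PAF"))))
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(y, k, seed = NULL) {
  assign_f <- function() {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
  if (is.null(seed)) assign_f() else with_seed(seed, assign_f())
}

#' Stratified k-fold cross-validation of a PAF ensemble
#'
#' Stratified tenfold split under a fixed seed; per fold, the full
#' training procedure (including median imputation) runs on the
#' remaining folds and the held-out fold is scored. The report pools the
#' confusion matrix and scores across folds (with 2-decimal granularity
#' on a 100-subject cohort, pooled counts are the faithful summary);
#' per-fold metrics are also retained.
#'
#' @param data Feature data frame with a `label` column in
#'   `{PAF, normal}` and numeric feature columns.
#' @param method Ensemble method, see [paf_ensemble()].
#' @param folds Number of folds (default 10); reduced with a warning if
#'   a class has fewer samples than folds.
#' @param seed Seed controlling the fold split and fold-wise training.
#' @param ... Passed on to [paf_ensemble()].
#' @return An object of class `paf_cv`: pooled `metrics` (7 indicators,
#'   with both F1 conventions), `auroc`, the pooled `confusion` matrix,
#'   `per_fold` data frame, and pooled `scores`/`labels`.
#' @export
cross_validate <- function(data, method = c("bagging", "adaboost", "stacking"),
                           folds = 10, seed = 1, ...) {
  method <- match.arg(method)
  y <- as.character(data$label)
  if (length(unique(y)) < 2L)
    stopf("domain error: cross-validation needs both classes")
  minc <- min(table(y))
  if (minc < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    folds, minc))
    folds <- minc
  }
  fold <- stratified_folds(y, folds, seed = derive_seed(seed, 77L))
  scores <- numeric(length(y))
  preds <- character(length(y))
  per_fold <- vector("list", folds)
  feats <- setdiff(names(data), c("label", "subject_id"))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- paf_ensemble(label ~ ., data[tr, c(feats, "label")],
                        method = method, seed = derive_seed(seed, f), ...)
    s <- predict(fit, data[!tr, feats, drop = FALSE], type = "score")
    scores[!tr] <- s
    preds[!tr] <- ifelse(s >= 0.5, "PAF", "normal")
    mf <- confusion_metrics(confusion_matrix(y[!tr], preds[!tr]))
    per_fold[[f]] <- data.frame(fold = f, n = sum(!tr),
                                accuracy = mf$accuracy)
  }
  cm <- confusion_matrix(y, preds)
  structure(list(method = method, folds = folds, seed = seed,
                 metrics = confusion_metrics(cm),
                 auroc = auroc(scores, y),
                 confusion = cm,
                 per_fold = do.call(rbind, per_fold),
                 scores = scores, labels = y, fold = fold),
            class = "paf_cv")
}

#' @export
print.paf_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%d-fold cross-validation, %s ensemble (n = %d)\n",
              x$folds, x$method, length(x$labels)))
  cat(sprintf(
    "  accuracy %.2f  sensitivity %.2f  specificity %.2f\n  PPV %.4f  NPV %.4f  F1(neg) %.4f  F1(pos) %.4f  AUROC %.4f\n",
    m$accuracy, m$sensitivity, m$specificity, m$PPV, m$NPV,
    m$F1_negative, m$F1_positive, x$auroc))
  invisible(x)
}

#' @export
summary.paf_cv <- function(object, ...) {
  print(object)
  cat("  pooled confusion matrix:\n")
  print(object$confusion)
  cat("  per-fold accuracy:\n")
  print(object$per_fold, row.names = FALSE)
  invisible(object)
}

#' @param x A `paf_cv` object.
#' @param ... Passed to [graphics::plot()].
#' @describeIn cross_validate ROC curve of the pooled cross-validated
#'   scores.
#' @export
plot.paf_cv <- function(x, ...) {
  rp <- roc_points(x$scores, x$labels)
  graphics::plot(rp$FPR, rp$TPR, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s: AUROC = %.3f", x$method, x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Side-by-side comparison of the three ensemble methods
#'
#' Runs [cross_validate()] for each requested method on one feature
#' table and assembles the seven indicators in a comparison table
#' (methods as rows), the headline F1 column being the
#' negative-class convention with the positive-class F1 alongside.
#'
#' @param data Labeled feature data frame.
#' @param methods Methods to compare.
#' @param folds,seed,... Passed to [cross_validate()].
#' @return Data frame of class `paf_comparison`.
#' @export
compare_ensembles <- function(data,
                              methods = c("bagging", "adaboost", "stacking"),
                              folds = 10, seed = 1, ...) {
  rows <- lapply(methods, function(m) {
    cv <- cross_validate(data, method = m, folds = folds, seed = seed, ...)
    data.frame(model = m, accuracy = cv$metrics$accuracy,
               sensitivity = cv$metrics$sensitivity,
               specificity = cv$metrics$specificity,
               PPV = cv$metrics$PPV, NPV = cv$metrics$NPV,
               F1 = cv$metrics$F1_negative,
               F1_positive = cv$metrics$F1_positive,
               AUROC = cv$auroc)
  })
  structure(do.call(rbind, rows), class = c("paf_comparison", "data.frame"))
}
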