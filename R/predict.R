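#' Rank-based AUC of a score
#'
#' Mann-Whitney AUC: the probability that a random positive outranks a random
#' negative, with ties counted half. For a hard binary prediction used as the
#' score this equals (sensitivity + specificity) / 2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param y_true Binary truth (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, y_true) {
  y <- as.integer(as.logical(y_true))
  if (length(scores) != length(y)) abort("length mismatch", "invalid_input")
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC undefined: truth contains a single class", "undefined_auc")
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics for a binary classifier
#'
#' Accuracy, precision, sensitivity, F1 (harmonic mean of precision and
#' sensitivity) and AUC. The AUC is the rank statistic of the binary
#' predictions themselves, which for a hard classifier equals
#' (sensitivity + specificity) / 2. Zero-division conventions: precision is 0
#' when nothing is predicted positive; F1 is 0 when precision + sensitivity
#' is 0.
#'
#' @param y_pred Binary predictions (0/1 or logical).
#' @param y_true Binary truth, same length; must contain both classes when
#'   `auc = TRUE`.
#' @param auc Compute the AUC (default `TRUE`); with `FALSE`, single-class
#'   truth is tolerated and `auc` is returned as `NA`.
#' @return Named list: `accuracy`, `precision`, `sensitivity`, `f1`, `auc`.
#' @export
binary_metrics <- function(y_pred, y_true, auc = TRUE) {
  yp <- as.integer(as.logical(y_pred))
  yt <- as.integer(as.logical(y_true))
  if (length(yp) != length(yt)) {
    abort("`y_pred` and `y_true` must have the same length", "invalid_input")
  }
  if (anyNA(yp) || anyNA(yt)) abort("predictions/truth contain NA", "invalid_input")
  tp <- sum(yp == 1L & yt == 1L)
  fp <- sum(yp == 1L & yt == 0L)
  fn <- sum(yp == 0L & yt == 1L)
  tn <- sum(yp == 0L & yt == 0L)
  accuracy <- (tp + tn) / length(yt)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  sensitivity <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(sensitivity) || precision + sensitivity == 0) {
    if (is.na(sensitivity)) NA_real_ else 0
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  auc_val <- if (auc) rank_auc(yp, yt) else NA_real_
  list(accuracy = accuracy, precision = precision, sensitivity = sensitivity,
       f1 = f1, auc = auc_val)
}

#' Fit a threshold classifier by exhaustive AUC search
#'
#' The classifier predicts a positive outcome when the feature exceeds a
#' cut-off theta (orientation fixed). Training enumerates the finite set of
#' candidate thresholds that can produce distinct predictions — midpoints of
#' consecutive sorted distinct feature values, plus one candidate below the
#' minimum and one above the maximum — and keeps the theta maximizing the
#' rank-AUC of the resulting predictions, breaking ties toward the smallest
#' theta. This midpoint set is exhaustive: any finer grid yields the same
#' prediction vectors.
#'
#' @param x Numeric feature values.
#' @param y Binary labels containing both classes.
#' @param feature_name Stored label for the feature (default `"feature"`).
#' @return An object of class `threshold_model` with `theta`, `train_auc`,
#'   `feature_name`.
#' @export
fit_threshold <- function(x, y, feature_name = "feature") {
  x <- as.numeric(x)
  y <- as.integer(as.logical(y))
  if (length(x) != length(y) || anyNA(x) || anyNA(y)) {
    abort("`x` and `y` must be NA-free and of equal length", "invalid_input")
  }
  if (length(unique(y)) < 2L) {
    abort("labels contain a single class; threshold cannot be trained",
          "degenerate_labels")
  }
  sx <- sort(unique(x))
  cands <- if (length(sx) == 1L) {
    c(sx - 1, sx + 1)
  } else {
    c(sx[1] - 1, (sx[-length(sx)] + sx[-1]) / 2, sx[length(sx)] + 1)
  }
  aucs <- vapply(cands, function(th) rank_auc(as.integer(x > th), y), numeric(1))
  best <- which(aucs >= max(aucs) - 1e-12)[1] # smallest optimal theta
  structure(list(feature_name = feature_name, theta = cands[best],
                 train_auc = aucs[best]),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model: positive when %s > %.4g (training AUC %.3f)>\n",
              x$feature_name, x$theta, x$train_auc))
  invisible(x)
}

#' Predict with a threshold model
#'
#' @param object A `threshold_model`.
#' @param newdata Numeric feature values.
#' @param ... Unused.
#' @return Integer 0/1 predictions.
#' @export
predict.threshold_model <- function(object, newdata, ...) {
  as.integer(as.numeric(newdata) > object$theta)
}

# Stratified, shuffled, seeded fold assignment.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validate the threshold classifier
#'
#' Stratified, shuffled, seeded k-fold cross-validation: per fold, the
#' threshold is calibrated on the k-1 training folds by exhaustive AUC search
#' and evaluated on the held-out fold. Stratification keeps both classes in
#' every test fold at modest cohort sizes; it is an assumption, flagged in
#' the methods vignette. A test fold that still ends up single-class has its
#' AUC recorded as missing and flagged.
#'
#' @param x Feature values.
#' @param y Binary labels (both classes present; `length(y) >= k`).
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed (default 1).
#' @param outcome_name,feature_name Labels carried into the report.
#' @return A `cv_report`: data.frame `folds` (per-fold theta + metrics +
#'   `flagged`), data.frame `summary` (mean and SD per metric and for theta),
#'   plus `k` and `seed`.
#' @export
cross_validate <- function(x, y, k = 5, seed = 1, outcome_name = "outcome",
                           feature_name = "feature") {
  x <- as.numeric(x)
  y <- as.integer(as.logical(y))
  n <- length(y)
  if (length(x) != n) abort("length mismatch", "invalid_input")
  if (n < k) abort("need at least k observations", "insufficient_data")
  if (length(unique(y)) < 2L) abort("single-class labels", "degenerate_labels")
  fold <- stratified_folds(y, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    te <- fold == f
    model <- fit_threshold(x[tr], y[tr], feature_name)
    pred <- predict(model, x[te])
    single <- length(unique(y[te])) < 2L
    m <- binary_metrics(pred, y[te], auc = !single)
    data.frame(fold = f, theta = model$theta, accuracy = m$accuracy,
               precision = m$precision, sensitivity = m$sensitivity,
               f1 = m$f1, auc = m$auc, flagged = single)
  })
  folds <- do.call(rbind, rows)
  metric_cols <- c("theta", "accuracy", "precision", "sensitivity", "f1", "auc")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(folds[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL
  )
  structure(list(outcome_name = outcome_name, feature_name = feature_name,
                 folds = folds, summary = summary, k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of '%s' predicting '%s' (seed %d)\n",
              x$k, x$feature_name, x$outcome_name, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.2f ± %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  if (any(x$folds$flagged)) {
    cat(sprintf("  (%d fold(s) had single-class truth; AUC missing there)\n",
                sum(x$folds$flagged)))
  }
  invisible(x)
}

#' Compare two cross-validated models by their fold AUCs
#'
#' Unpaired pooled t-test on the two per-fold AUC samples.
#'
#' @param report_a,report_b `cv_report` objects with at least 2 folds of
#'   defined AUC each.
#' @return A `ttest_result`.
#' @export
compare_models <- function(report_a, report_b) {
  a <- report_a$folds$auc
  b <- report_b$folds$auc
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("each report needs at least 2 folds with defined AUC",
          "insufficient_data")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      # identical constant AUCs: no evidence of a difference
      return(new_ttest_result(0, length(a) + length(b) - 2, 1,
                              c(mean(a), 0, length(a)),
                              c(mean(b), 0, length(b))))
    }
    abort("zero within-group variance in fold AUCs; t-test undefined",
          "insufficient_variance")
  }
  pooled_t_test(a, b)
}
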