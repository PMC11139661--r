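test_that("binary_metrics matches hand-computed confusion matrices", {
  perfect <- binary_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1,
                                  sensitivity = 1, f1 = 1, auc = 1))

  allneg <- binary_metrics(rep(0, 10), rep(c(1, 0), 5))
  expect_equal(allneg$accuracy, 0.5)
  expect_equal(allneg$precision, 0) # zero predicted positives convention
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$f1, 0)
  expect_equal(allneg$auc, 0.5)

  # TP=3, FP=1, FN=2, TN=4
  y_true <- c(rep(1, 5), rep(0, 5))
  y_pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m <- binary_metrics(y_pred, y_true)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$auc, (0.6 + 0.8) / 2)

  expect_error(binary_metrics(c(1, 0), c(1, 0, 1)),
               class = "blastonet_invalid_input")
  expect_error(binary_metrics(c(1, 0), c(1, 1)),
               class = "blastonet_undefined_auc")
  no_auc <- binary_metrics(c(1, 0), c(1, 1), auc = FALSE)
  expect_true(is.na(no_auc$auc))
})

test_that("prediction-AUC identity: rank AUC == (sens + spec)/2 always", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    y <- c(1, 0, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    pred <- rbinom(n, 1, 0.5)
    m <- binary_metrics(pred, y)
    spec <- sum(pred == 0 & y == 0) / sum(y == 0)
    expect_equal(m$auc, (m$sensitivity + spec) / 2, tolerance = 1e-12)
  }
})

test_that("fit_threshold: midpoint candidates, tie-breaks, inverted labels", {
  m <- fit_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(m$theta, 2.5)
  expect_equal(m$train_auc, 1)

  # inverted labels: fixed orientation cannot do better than AUC 0.5,
  # achieved at the below-minimum candidate (predict everything positive)
  inv <- fit_threshold(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(inv$train_auc, 0.5)
  expect_equal(inv$theta, 0) # smallest optimal candidate = min(x) - 1

  # predictions flow through predict()
  expect_equal(predict(m, c(0, 2.4, 2.6, 9)), c(0L, 0L, 1L, 1L))

  expect_error(fit_threshold(1:4, c(1, 1, 1, 1)),
               class = "blastonet_degenerate_labels")
})

test_that("fit_threshold equals the brute-force grid oracle", {
  set.seed(90)
  for (i in 1:60) {
    n <- 40
    x <- round(rnorm(n, 3, 0.6), 2) # duplicated values exercise midpoints
    y <- rbinom(n, 1, plogis((x - 3) * runif(1, -2, 3)))
    if (length(unique(y)) < 2) next
    model <- fit_threshold(x, y)
    expect_equal(model$train_auc, grid_fit_threshold(x, y), tolerance = 1e-9)
  }
})

test_that("cross_validate separates a strong signal and stays null on noise", {
  set.seed(5)
  x <- c(rnorm(50, 3.3, 0.1), rnorm(50, 2.9, 0.1))
  y <- rep(c(1, 0), each = 50)
  rep_ <- cross_validate(x, y, k = 5, seed = 2)
  expect_equal(nrow(rep_$folds), 5)
  expect_gte(rep_$summary$mean[rep_$summary$metric == "auc"], 0.95)
  expect_true(all(rep_$folds$theta > 2.9 & rep_$folds$theta < 3.3))

  # permuted labels: chance-level AUC
  set.seed(6)
  xp <- rnorm(200)
  yp <- sample(rep(c(1, 0), each = 100))
  null_rep <- cross_validate(xp, yp, k = 5, seed = 3)
  expect_equal(null_rep$summary$mean[null_rep$summary$metric == "auc"], 0.5,
               tolerance = 0.1)

  # determinism
  again <- cross_validate(x, y, k = 5, seed = 2)
  expect_identical(rep_, again)
  shuffled <- cross_validate(x, y, k = 5, seed = 99)
  expect_false(identical(rep_$folds, shuffled$folds))
})

test_that("cross_validate stratifies and flags single-class folds", {
  set.seed(41)
  x <- rnorm(40)
  y <- c(rep(1, 8), rep(0, 32)) # 20% positives, stratification keeps ~1-2/fold
  rep_ <- cross_validate(x, y, k = 5, seed = 7)
  per_fold_pos <- tapply(y, blastonet:::stratified_folds(y, 5, 7), sum)
  expect_true(all(per_fold_pos >= 1))

  # degenerate: only 2 positives among 20 -> some folds lack positives
  y2 <- c(rep(1, 2), rep(0, 18))
  x2 <- rnorm(20)
  rep2 <- cross_validate(x2, y2, k = 5, seed = 1)
  expect_true(any(rep2$folds$flagged))
  expect_true(all(is.na(rep2$folds$auc[rep2$folds$flagged])))

  expect_error(cross_validate(rnorm(3), c(1, 0, 1), k = 5),
               class = "blastonet_insufficient_data")
  expect_error(cross_validate(rnorm(10), rep(1, 10)),
               class = "blastonet_degenerate_labels")
})

test_that("compare_models delegates to the pooled t-test", {
  mk <- function(aucs) {
    structure(list(outcome_name = "o", feature_name = "f",
                   folds = data.frame(fold = seq_along(aucs), auc = aucs),
                   k = length(aucs), seed = 1),
              class = "cv_report")
  }
  a <- mk(c(0.91, 0.88, 0.93, 0.90, 0.89))
  b <- mk(c(0.55, 0.60, 0.50, 0.58, 0.52))
  cmp <- compare_models(a, b)
  ref <- t.test(a$folds$auc, b$folds$auc, var.equal = TRUE)
  expect_equal(cmp$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cmp$degrees_of_freedom, 8L)

  # identical fold AUCs: t = 0, p = 1 (even when within-group variance is 0)
  same <- compare_models(mk(c(0.7, 0.7, 0.7, 0.7, 0.7)),
                         mk(c(0.7, 0.7, 0.7, 0.7, 0.7)))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # distinct constant AUCs: zero pooled variance is an error
  expect_error(compare_models(mk(rep(0.9, 5)), mk(rep(0.5, 5))),
               class = "blastonet_insufficient_variance")
  expect_error(compare_models(mk(0.8), mk(c(0.5, 0.6))),
               class = "blastonet_insufficient_data")
})
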