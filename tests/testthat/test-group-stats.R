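test_that("gardner_quality implements the good/poor rule", {
  expect_equal(gardner_quality("4AB"), "good")
  expect_equal(gardner_quality("3BC"), "poor") # TE = C fails
  expect_equal(gardner_quality("2AA"), "poor") # expansion 2 fails
  expect_equal(gardner_quality("3CB"), "poor") # ICM = C fails
  expect_equal(gardner_quality(c("5AA", "6BB", "1", "2")),
               c("good", "good", "poor", "poor"))
  expect_equal(gardner_quality("4ab"), "good") # case-insensitive
  expect_error(gardner_quality("7AA"), class = "blastonet_parse_error")
  expect_error(gardner_quality("AB4"), class = "blastonet_parse_error")
  expect_error(gardner_quality("4A"), class = "blastonet_parse_error")
  expect_error(gardner_quality(""), class = "blastonet_parse_error")
})

test_that("pooled_t_test agrees with the classical formula and t.test", {
  tt <- pooled_t_test(c(1, 2, 3), c(4, 5, 6))
  # diff 3, sp^2 = 1, SE = sqrt(2/3)
  expect_equal(abs(tt$t_statistic), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$degrees_of_freedom, 4L)

  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    got <- pooled_t_test(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$degrees_of_freedom, unname(ref$parameter))
    # antisymmetry
    swapped <- pooled_t_test(y, x)
    expect_equal(swapped$t_statistic, -got$t_statistic)
    expect_equal(swapped$p_value, got$p_value)
  }

  same <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("summary and raw forms are algebraically identical", {
  set.seed(77)
  for (i in 1:100) {
    x <- rnorm(sample(3:30, 1))
    y <- rnorm(sample(3:30, 1), mean = 0.3)
    raw <- pooled_t_test(x, y)
    summ <- pooled_t_from_summary(mean(x), sd(x), length(x),
                                  mean(y), sd(y), length(y))
    expect_equal(raw$t_statistic, summ$t_statistic, tolerance = 1e-12)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  }
  degenerate <- pooled_t_from_summary(2, 1, 10, 2, 1, 10)
  expect_equal(degenerate$t_statistic, 0)
  expect_error(pooled_t_from_summary(1, 1, 1, 2, 1, 10),
               class = "blastonet_insufficient_data")
  expect_error(pooled_t_from_summary(1, 0, 10, 2, 0, 10),
               class = "blastonet_insufficient_data")
  expect_error(pooled_t_test(c(1), c(2, 3)),
               class = "blastonet_insufficient_data")
})

test_that("pooled t-test maintains its nominal type-I error", {
  set.seed(55)
  n_sim <- 1000
  n <- 30
  # vectorized null simulation: equal means, equal variances
  x <- matrix(rnorm(n_sim * n), n_sim)
  y <- matrix(rnorm(n_sim * n), n_sim)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, var); vy <- apply(y, 1, var)
  sp2 <- ((n - 1) * vx + (n - 1) * vy) / (2 * n - 2)
  tstat <- (mx - my) / sqrt(sp2 * 2 / n)
  p <- 2 * pt(-abs(tstat), 2 * n - 2)
  # spot-check one replicate against the package implementation
  got <- pooled_t_test(x[1, ], y[1, ])
  expect_equal(got$t_statistic, tstat[1], tolerance = 1e-12)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.02)
})

test_that("spearman_bootstrap: monotone limits, determinism, errors", {
  x <- 1:20
  up <- spearman_bootstrap(x, x + 0.5, n_boot = 200, seed = 1)
  expect_equal(up$rho, 1)
  expect_equal(up$ci_low, 1)
  expect_equal(up$ci_high, 1)
  down <- spearman_bootstrap(x, rev(x), n_boot = 50, seed = 1)
  expect_equal(down$rho, -1)

  set.seed(12)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40)
  r1 <- spearman_bootstrap(a, b, n_boot = 500, seed = 42)
  r2 <- spearman_bootstrap(a, b, n_boot = 500, seed = 42)
  expect_identical(r1, r2)
  expect_lt(r1$ci_low, r1$rho)
  expect_gt(r1$ci_high, r1$rho)
  expect_equal(r1$rho, cor(a, b, method = "spearman"))

  expect_error(spearman_bootstrap(rep(1, 10), rnorm(10)),
               class = "blastonet_undefined_correlation")
  expect_error(spearman_bootstrap(1:2, 1:2),
               class = "blastonet_insufficient_data")
})

test_that("compare_outcome splits groups and gates transfers", {
  set.seed(9)
  df <- data.frame(
    embryo_id = sprintf("e%02d", 1:40),
    mean_contacts = c(rnorm(20, 3.3, 0.5), rnorm(20, 2.9, 0.5)),
    quality = rep(c("good", "poor"), each = 20),
    live_birth = rep(c(TRUE, FALSE), each = 20),
    transferred = rep(c(TRUE, FALSE), times = 20)
  )
  row <- compare_outcome(df, "quality")
  expect_equal(row$n_1, 20)
  expect_equal(row$n_2, 20)
  expect_equal(row$df, 38)
  # transfer gating halves the live-birth comparison
  row2 <- compare_outcome(df, "live_birth")
  expect_equal(row2$n_1 + row2$n_2, 20)
  expect_error(compare_outcome(df, "nope"), class = "blastonet_invalid_input")
})

test_that("outcome_record enforces its invariants", {
  r <- outcome_record("e1", gardner = "4AB", transferred = TRUE,
                      live_birth = TRUE)
  expect_equal(r$quality, "good")
  expect_error(outcome_record("e2", live_birth = TRUE),
               class = "blastonet_invalid_parameter")
  expect_error(outcome_record("e3", gardner = "4AB", quality = "poor"),
               class = "blastonet_invalid_parameter")
})
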