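#' Parse a Gardner grade and dichotomize blastocyst quality
#'
#' A Gardner grade is an expansion digit (1-6) optionally followed by inner
#' cell mass and trophectoderm letters (A-C); the letters are only assigned
#' once the blastocyst is expanded enough to grade them (expansion >= 3), so
#' strings like `"2"` are legal. A blastocyst is "good" iff expansion > 2,
#' ICM better than C and TE better than C, i.e. expansion >= 3 with ICM and
#' TE in \{A, B\}; anything else is "poor".
#'
#' @param grade Gardner grade string(s), e.g. `"4AB"`.
#' @return Character vector of `"good"` / `"poor"`.
#' @export
gardner_quality <- function(grade) {
  vapply(as.character(grade), function(g) {
    g0 <- toupper(trimws(g))
    if (!grepl("^[1-6][A-C]{0,2}$", g0)) {
      abort(sprintf("unparseable Gardner grade: '%s'", g), "parse_error")
    }
    exp_ <- as.integer(substr(g0, 1, 1))
    icm <- substr(g0, 2, 2)
    te <- substr(g0, 3, 3)
    if (exp_ <= 2L) {
      # ICM/TE may be absent (or present); either way quality cannot be good
      return("poor")
    }
    if (icm == "" || te == "") {
      abort(sprintf("Gardner grade '%s': expansion >= 3 requires ICM and TE letters", g),
            "parse_error")
    }
    if (icm %in% c("A", "B") && te %in% c("A", "B")) "good" else "poor"
  }, character(1), USE.NAMES = FALSE)
}

new_ttest_result <- function(t, df, p, g1, g2) {
  structure(list(t_statistic = t, degrees_of_freedom = as.integer(df),
                 p_value = p,
                 group_summaries = data.frame(
                   group = c(1L, 2L),
                   mean = c(g1[1], g2[1]),
                   sd = c(g1[2], g2[2]),
                   n = as.integer(c(g1[3], g2[3])))),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Pooled two-sample t-test: t = %.3f, df = %d, p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  print(x$group_summaries, row.names = FALSE)
  invisible(x)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's equal-variance (pooled) unpaired t-test computed from group
#' means, SDs and sizes, with a two-sided p-value on n1 + n2 - 2 degrees of
#' freedom. The pooled (rather than Welch) form is used throughout: it is the
#' form that reproduces published t-statistics from printed group summaries
#' in this setting.
#'
#' @param m1,s1,n1 Mean, SD (denominator n-1) and size of group 1.
#' @param m2,s2,n2 Same for group 2.
#' @return A `ttest_result` with elements `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `group_summaries`.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) {
    abort("both groups need at least 2 observations", "insufficient_data")
  }
  if (!is_scalar_num(s1) || !is_scalar_num(s2) || s1 < 0 || s2 < 0) {
    abort("SDs must be non-negative numbers", "insufficient_data")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 <= 0) {
    abort("pooled variance is zero", "insufficient_data")
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df)
  new_ttest_result(t, df, p, c(m1, s1, n1), c(m2, s2, n2))
}

#' Pooled two-sample t-test on raw samples
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return A `ttest_result`; identical to [pooled_t_from_summary()] applied
#'   to the samples' moments.
#' @export
pooled_t_test <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) abort("samples contain NA", "insufficient_data")
  if (length(x) < 2 || length(y) < 2) {
    abort("both samples need at least 2 observations", "insufficient_data")
  }
  pooled_t_from_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y))
}

#' Bootstrap Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties, plus a percentile bootstrap
#' confidence interval over paired resamples. Percentile (rather than BCa)
#' intervals are an assumption documented in the methods vignette. Resamples
#' in which either margin is constant yield an undefined correlation and are
#' dropped from the percentile computation.
#'
#' @param x,y Paired numeric samples, length >= 3.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed; the interval is deterministic given it.
#' @return List with `rho`, `ci_low`, `ci_high`, `conf`, `n_boot`,
#'   `n_dropped`.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 10000, conf = 0.95, seed = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must be paired", "invalid_parameter")
  if (n < 3) abort("need at least 3 pairs", "insufficient_data")
  if (anyNA(x) || anyNA(y)) abort("samples contain NA", "insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant sample", "undefined_correlation")
  }
  rho <- stats::cor(x, y, method = "spearman")
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]
      yb <- y[idx]
      if (stats::sd(xb) == 0 || stats::sd(yb) == 0) return(NA_real_)
      stats::cor(xb, yb, method = "spearman")
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(rho = rho, ci_low = ci[1], ci_high = ci[2], conf = conf,
       n_boot = n_boot, n_dropped = sum(is.na(boots)))
}

#' Outcome record for one embryo
#'
#' Container for per-embryo clinical labels. Live birth and miscarriage may
#' only be set for transferred embryos (miscarriage meaning loss of a
#' clinical pregnancy within the first 20 weeks); `quality` is derived from
#' the Gardner grade when a grade is present.
#'
#' @param embryo_id Identifier.
#' @param blastulated,transferred,biochemical_pregnancy,live_birth,miscarriage,euploid
#'   Optional logical labels (`NA` = unknown).
#' @param gardner Optional Gardner grade string.
#' @param quality Optional `"good"`/`"poor"`; filled from `gardner` if absent.
#' @return An object of class `outcome_record`.
#' @export
outcome_record <- function(embryo_id, blastulated = NA, gardner = NA_character_,
                           quality = NA_character_, transferred = FALSE,
                           biochemical_pregnancy = NA, live_birth = NA,
                           miscarriage = NA, euploid = NA) {
  if (!is.na(gardner) && is.na(quality)) {
    quality <- gardner_quality(gardner)
  }
  if (!is.na(quality) && !is.na(gardner) && quality != gardner_quality(gardner)) {
    abort(sprintf("quality '%s' inconsistent with Gardner grade '%s'",
                  quality, gardner), "invalid_parameter")
  }
  if (!isTRUE(transferred) && (isTRUE(live_birth) || isFALSE(live_birth) ||
                               isTRUE(miscarriage) || isFALSE(miscarriage))) {
    abort("live_birth/miscarriage may only be set for transferred embryos",
          "invalid_parameter")
  }
  structure(list(embryo_id = as.character(embryo_id),
                 blastulated = blastulated, gardner = gardner,
                 quality = quality, transferred = isTRUE(transferred),
                 biochemical_pregnancy = biochemical_pregnancy,
                 live_birth = live_birth, miscarriage = miscarriage,
                 euploid = euploid),
            class = "outcome_record")
}

#' Compare the contact biomarker across an outcome
#'
#' Splits embryos by a binary outcome column and runs the pooled t-test on
#' their biomarker values. Pregnancy, live-birth and miscarriage comparisons
#' are restricted to transferred embryos.
#'
#' @param data data.frame with at least the biomarker column and the outcome
#'   column; a logical `transferred` column is required for transfer-gated
#'   outcomes.
#' @param outcome Name of the outcome column. Logical/0-1 columns compare
#'   TRUE vs FALSE; a `quality` column compares `"good"` vs `"poor"`.
#' @param biomarker Name of the biomarker column (default `"mean_contacts"`).
#' @return A one-row data.frame: comparison, group means/SDs/sizes, t, df, p.
#' @export
compare_outcome <- function(data, outcome, biomarker = "mean_contacts") {
  if (!outcome %in% names(data)) {
    abort(sprintf("outcome column '%s' not found", outcome), "invalid_input")
  }
  if (!biomarker %in% names(data)) {
    abort(sprintf("biomarker column '%s' not found", biomarker), "invalid_input")
  }
  transfer_gated <- outcome %in% c("biochemical_pregnancy", "live_birth",
                                   "miscarriage")
  if (transfer_gated) {
    if (!"transferred" %in% names(data)) {
      abort("transfer-gated outcomes need a `transferred` column", "invalid_input")
    }
    data <- data[!is.na(data$transferred) & data$transferred, , drop = FALSE]
  }
  v <- data[[outcome]]
  if (is.character(v) || is.factor(v)) {
    v <- as.character(v)
    pos <- v == "good"
    neg <- v == "poor"
  } else {
    pos <- !is.na(v) & as.logical(v)
    neg <- !is.na(v) & !as.logical(v)
  }
  x <- data[[biomarker]][pos]
  y <- data[[biomarker]][neg]
  tt <- pooled_t_test(x, y)
  data.frame(comparison = outcome,
             mean_1 = mean(x), sd_1 = stats::sd(x), n_1 = length(x),
             mean_2 = mean(y), sd_2 = stats::sd(y), n_2 = length(y),
             t_statistic = tt$t_statistic, df = tt$degrees_of_freedom,
             p_value = tt$p_value, stringsAsFactors = FALSE)
}
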