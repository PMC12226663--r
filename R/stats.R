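#' Percent change from baseline
#'
#' Responsiveness expressed as the decline of the group mean relative to
#' baseline: `100 * (baseline - followup) / baseline`, positive for a
#' decrease, reported to the nearest integer percent (the study's
#' reporting precision).
#'
#' @param baseline_mean baseline group mean (> 0).
#' @param followup_mean follow-up group mean.
#' @param digits rounding digits (default 0, i.e. integer percent); use
#'   `NULL` for full precision.
#' @return Percent change (vectorized over the means).
#' @export
percent_change <- function(baseline_mean, followup_mean, digits = 0) {
  if (any(!is.finite(baseline_mean)) || any(baseline_mean <= 0)) {
    stopf("`baseline_mean` must be positive")
  }
  pc <- 100 * (baseline_mean - followup_mean) / baseline_mean
  if (is.null(digits)) pc else round(pc, digits)
}

#' Mixed-effects change over time
#'
#' Tests whether a measurement changed over the study timepoints with a
#' linear mixed-effects model for repeated measures: a fixed categorical
#' timepoint effect and a random per-subject intercept, fitted by
#' restricted maximum likelihood.  Subjects with missing follow-up visits
#' contribute their available data (likelihood-based handling, no
#' imputation).  The p-value is the joint Satterthwaite F-test of the
#' timepoint terms.
#'
#' @param table a longitudinal table ([as_longitudinal_table()]).
#' @param measurement name of the measurement column to model.
#' @return An object of class `change_test`: `measurement`, `means`
#'   (model-implied timepoint means), `p_value`, `fixed_effects`,
#'   `n_subjects`, `n_obs`, and the fitted `model`.
#' @export
fit_change_over_time <- function(table, measurement) {
  table <- as_longitudinal_table(table)
  if (!measurement %in% names(table)) {
    stopf("measurement `%s` is not a column of the table", measurement)
  }
  d <- table[!is.na(table[[measurement]]),
             c("subject_id", "timepoint", measurement)]
  names(d)[3L] <- "value"
  n_tp <- tapply(d$timepoint, d$subject_id, function(x) length(unique(x)))
  if (length(unique(d$subject_id)) < 2L || !any(n_tp >= 2L, na.rm = TRUE)) {
    stopf("need at least 2 subjects, at least one with repeated visits")
  }
  d$timepoint <- droplevels(d$timepoint)
  fit <- lmerTest::lmer(value ~ timepoint + (1 | subject_id), data = d,
                        REML = TRUE)
  an <- anova(fit)   # Satterthwaite by default
  p <- an[["Pr(>F)"]][1L]
  fe <- lme4::fixef(fit)
  tps <- levels(d$timepoint)
  means <- stats::setNames(rep(fe[[1L]], length(tps)), tps)
  for (i in seq_along(tps)[-1L]) {
    term <- paste0("timepoint", tps[i])
    if (term %in% names(fe)) means[i] <- fe[[1L]] + fe[[term]]
  }
  structure(list(measurement = measurement, means = means, p_value = p,
                 fixed_effects = fe,
                 n_subjects = length(unique(d$subject_id)),
                 n_obs = nrow(d), model = fit),
            class = "change_test")
}

#' @export
print.change_test <- function(x, ...) {
  cat(sprintf("<change_test> %s: %s; p = %.4g (joint timepoint F-test)\n",
              x$measurement,
              paste(sprintf("%s %.1f", names(x$means), x$means),
                    collapse = " vs. "),
              x$p_value))
  invisible(x)
}

# ICC(2,1): two-way random effects, absolute agreement, single measures,
# from the two-way ANOVA mean squares; confidence interval by the
# F-distribution method (McGraw & Wong).
icc21 <- function(m, conf_level = 0.95) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lower = lower, upper = upper,
       msr = msr, msc = msc, mse = mse)
}

icc_band <- function(icc) {
  if (icc < 0.50) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.90) "good"
  else "excellent"
}

#' Intraclass-correlation agreement between two raters
#'
#' Agreement between co-indexed measurements of the same targets by two
#' methods (e.g. manual and semi-automated wall volume), as the two-way
#' random-effects, absolute-agreement, single-measures intraclass
#' correlation ICC(2,1) computed from the two-way ANOVA mean squares,
#' with an F-distribution 95% confidence interval.  The qualitative band
#' follows the conventional thresholds: below 0.50 poor, 0.50-0.75
#' moderate, 0.75-0.90 good, above 0.90 excellent.
#'
#' @param x,y numeric vectors of paired measurements; incomplete pairs
#'   are dropped (at least 5 complete pairs required).
#' @param conf_level confidence level for the interval.
#' @return An object of class `icc_agreement`: `icc`, `ci_low`,
#'   `ci_high`, `band`, `n_pairs`, mean squares.
#' @export
icc_agreement <- function(x, y, conf_level = 0.95) {
  ok <- complete.cases(x, y)
  m <- cbind(x[ok], y[ok])
  if (nrow(m) < 5L) stopf("need at least 5 complete pairs (got %d)", nrow(m))
  if (var(m[, 1L]) == 0 && var(m[, 2L]) == 0) {
    stopf("ICC is undefined: both raters have zero variance")
  }
  res <- icc21(m, conf_level)
  structure(list(icc = res$icc, ci_low = res$lower, ci_high = res$upper,
                 band = icc_band(res$icc), n_pairs = nrow(m),
                 mean_squares = c(rows = res$msr, cols = res$msc,
                                  error = res$mse),
                 conf_level = conf_level),
            class = "icc_agreement")
}

#' @export
print.icc_agreement <- function(x, ...) {
  cat(sprintf("<icc_agreement> ICC(2,1) = %.2f [%.0f%% CI: %.2f-%.2f], %s (n = %d)\n",
              x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$band,
              x$n_pairs))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pearson's r between two measurements, with the two-sided test and the
#' Fisher z-transform confidence interval; incomplete pairs are dropped
#' pairwise.
#'
#' @param x,y numeric vectors (at least 4 complete pairs).
#' @param conf_level confidence level.
#' @return An object of class `pearson_ci`: `r`, `ci_low`, `ci_high`,
#'   `p_value`, `n_pairs`.
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stopf("need at least 4 complete pairs (got %d)",
                            length(x))
  if (var(x) == 0 || var(y) == 0) {
    stopf("correlation is undefined: zero variance")
  }
  ct <- cor.test(x, y, method = "pearson", conf.level = conf_level)
  structure(list(r = unname(ct$estimate), ci_low = ct$conf.int[1L],
                 ci_high = ct$conf.int[2L], p_value = ct$p.value,
                 n_pairs = length(x), conf_level = conf_level),
            class = "pearson_ci")
}

#' @export
print.pearson_ci <- function(x, ...) {
  cat(sprintf("<pearson_ci> r = %.2f (%.2f-%.2f) [p = %.3g], n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p_value, x$n_pairs))
  invisible(x)
}
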