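test_that("percent change reproduces the printed group-mean declines exactly", {
  pc <- printed_percent_changes()
  got <- percent_change(pc$baseline, pc$followup)
  expect_identical(got, pc$expected)
  expect_equal(percent_change(12.3, 12.3), 0)
  expect_error(percent_change(0, 5), "positive")
  expect_error(percent_change(-2, 5), "positive")
})

test_that("ICC equals the ANOVA mean-squares oracle and bands correctly", {
  set.seed(41)
  x <- rnorm(8, 10, 3)
  y <- x + rnorm(8, 0.5, 1)
  res <- icc_agreement(x, y)

  # independent oracle: two-way ANOVA via stats::aov
  long <- data.frame(v = c(x, y), s = factor(rep(1:8, 2)),
                     r = factor(rep(1:2, each = 8)))
  ms <- anova(stats::aov(v ~ s + r, long))[["Mean Sq"]]
  icc_oracle <- (ms[1] - ms[3]) /
    (ms[1] + (2 - 1) * ms[3] + 2 * (ms[2] - ms[3]) / 8)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-9)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)

  ident <- icc_agreement(1:6, 1:6)
  expect_equal(ident$icc, 1)
  expect_equal(ident$band, "excellent")

  set.seed(42)
  a <- rnorm(30, 10, 1)
  noisy <- icc_agreement(a, a + rnorm(30, 0, 20))
  expect_equal(noisy$band, "poor")

  expect_error(icc_agreement(rep(3, 6), rep(3, 6)), "zero variance")
  expect_error(icc_agreement(1:4, 2:5), "at least 5")
})

test_that("ICC matches the oracle over fuzzed small tables", {
  set.seed(7)
  for (rep in seq_len(200)) {
    n <- sample(5:12, 1)
    x <- rnorm(n, 10, runif(1, 0.5, 5))
    y <- runif(1, 0.5, 1.5) * x + rnorm(n, 0, runif(1, 0.1, 3))
    res <- icc_agreement(x, y)
    long <- data.frame(v = c(x, y), s = factor(rep(seq_len(n), 2)),
                       r = factor(rep(1:2, each = n)))
    ms <- anova(stats::aov(v ~ s + r, long))[["Mean Sq"]]
    icc_oracle <- (ms[1] - ms[3]) /
      (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / n)
    expect_equal(res$icc, icc_oracle, tolerance = 1e-9)
  }
})

test_that("pearson_ci matches the closed-form Fisher-z computation", {
  expect_equal(pearson_ci(1:10, 2 * (1:10))$r, 1)
  expect_equal(pearson_ci(1:10, -(1:10))$r, -1)

  set.seed(9)
  x <- rnorm(10); y <- 0.6 * x + rnorm(10, 0, 0.8)
  res <- pearson_ci(x, y)
  n <- 10
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(res$r, r, tolerance = 1e-9)
  expect_equal(res$ci_low, tanh(z - qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(res$ci_high, tanh(z + qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(res$p_value, 2 * pt(-abs(tt), n - 2), tolerance = 1e-9)

  # pairwise deletion of missing values
  xm <- c(x, NA, 5); ym <- c(y, 2, NA)
  expect_equal(pearson_ci(xm, ym)$n_pairs, 10L)

  expect_error(pearson_ci(rep(1, 8), rnorm(8)), "zero variance")
  expect_error(pearson_ci(1:3, 3:1), "at least 4")
})

test_that("change test rejects degenerate designs and handles missing visits", {
  tab <- make_longitudinal_cohort(n_subjects = 12, missingness = "study",
                                  rng_seed = 15)
  ct <- fit_change_over_time(tab, "manual_volume_mL")
  expect_equal(ct$n_subjects, 12L)
  expect_lt(ct$n_obs, 36L)
  expect_true(ct$p_value >= 0 && ct$p_value <= 1)
  expect_named(ct$means, c("baseline", "week6", "month6"))

  one <- tab[tab$subject_id == "S05", ]
  expect_error(fit_change_over_time(one, "manual_volume_mL"), "2 subjects")
  expect_error(fit_change_over_time(tab, "nonexistent"), "not a column")

  single_tp <- tab[tab$timepoint == "baseline", ]
  expect_error(fit_change_over_time(single_tp, "manual_volume_mL"),
               "repeated")
})

test_that("strong-decline cohorts are detected essentially always", {
  set.seed(61)
  seeds <- sample.int(2^31 - 2, 25)
  p <- vapply(seeds, function(s) {
    tab <- make_longitudinal_cohort(n_subjects = 20,
                                    timepoint_effects = c(1, 0.59, 0.26),
                                    rng_seed = s)
    fit_change_over_time(tab, "manual_volume_mL")$p_value
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.95)
})

test_that("the full study analysis bundles all statistics coherently", {
  tab <- make_longitudinal_cohort(n_subjects = 20, missingness = "study",
                                  rng_seed = 19)
  res <- run_study_analysis(tab)

  expect_named(res$change_tests,
               c("max_thickness_mm", "mean_thickness_mm", "length_cm",
                 "manual_volume_mL", "semiauto_volume_mL"))
  strong <- c("max_thickness_mm", "length_cm", "manual_volume_mL",
              "semiauto_volume_mL")
  for (m in strong) expect_lt(res$change_tests[[m]]$p_value, 0.05)

  # correlation matrix: symmetric, unit diagonal, r within CI bounds
  r <- res$correlations$r
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  for (p in res$correlations$pairs) {
    expect_true(p$ci_low <= p$r && p$r <= p$ci_high)
    expect_true(p$ci_low >= -1 && p$ci_high <= 1)
  }

  expect_s3_class(res$agreement, "icc_agreement")
  expect_gte(res$agreement$icc, 0.75)   # generator's agreement noise is mild

  # percent changes come from the group means
  gm <- res$group_means
  pcs <- res$percent_changes
  row <- pcs[pcs$measurement == "manual_volume_mL" &
               pcs$interval == "baseline_to_week6", ]
  expect_equal(row$percent_change,
               percent_change(gm["baseline", "manual_volume_mL"],
                              gm["week6", "manual_volume_mL"]))

  expect_error(run_study_analysis(tab[0, ]), "no measurement records")
  expect_output(print(res), "study_analysis")
})

test_that("all five measurements respond detectably under study conditions", {
  # The four strongly declining measurements reach significance in every
  # simulated cohort; mean wall thickness — the study's least responsive
  # measurement (8% / 28% declines) — does so in the majority.
  set.seed(71)
  seeds <- sample.int(2^31 - 2, 6)
  p <- sapply(seeds, function(s) {
    tab <- make_longitudinal_cohort(n_subjects = 20, missingness = "study",
                                    rng_seed = s)
    vapply(c("max_thickness_mm", "length_cm", "manual_volume_mL",
             "semiauto_volume_mL", "mean_thickness_mm"),
           function(m) fit_change_over_time(tab, m)$p_value, numeric(1))
  })
  expect_true(all(p[1:4, ] < 0.05))
  expect_gte(mean(p["mean_thickness_mm", ] < 0.05), 0.5)
})

test_that("per-subject percent change variant is reported alongside", {
  tab <- make_longitudinal_cohort(n_subjects = 10, rng_seed = 23)
  res <- run_study_analysis(tab, per_subject_change = TRUE)
  expect_true("per_subject_mean" %in% names(res$percent_changes))
  expect_true(all(is.finite(res$percent_changes$per_subject_mean)))
})
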