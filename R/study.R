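#' Run the full longitudinal study analysis
#'
#' Orchestrates the statistics layer over a longitudinal measurement
#' table: mixed-effects change-over-time tests for all five measurements,
#' group-mean percent changes from baseline to each follow-up,
#' intraclass-correlation agreement between manual and semi-automated
#' volume (all timepoints pooled), and the Pearson correlation matrix
#' between maximum wall thickness, length of disease, and the two volume
#' measures (all timepoints combined, pairwise deletion).
#'
#' @param table a longitudinal table ([as_longitudinal_table()]) with the
#'   five measurement columns; missing visits are used as available.
#' @param per_subject_change also compute the mean of per-subject percent
#'   changes (an alternative definition; the default group-mean form is
#'   the one whose results are reported).
#' @return An object of class `study_analysis`: `change_tests` (list of
#'   [fit_change_over_time()] results), `percent_changes` (data.frame),
#'   `agreement` ([icc_agreement()]), `correlations` (list: `r` matrix
#'   plus per-pair [pearson_ci()] results), `group_means`.
#' @export
run_study_analysis <- function(table, per_subject_change = FALSE) {
  table <- as_longitudinal_table(table)
  meas <- intersect(measurement_names(), names(table))
  if (nrow(table) == 0L || length(meas) == 0L) {
    stopf("the table has no measurement records to analyse")
  }

  change_tests <- lapply(meas, function(m) fit_change_over_time(table, m))
  names(change_tests) <- meas

  tps <- timepoint_levels()
  group_means <- sapply(meas, function(m) {
    tapply(table[[m]], table$timepoint, mean, na.rm = TRUE)[tps]
  })
  rownames(group_means) <- tps

  pc <- do.call(rbind, lapply(meas, function(m) {
    base <- group_means["baseline", m]
    out <- data.frame(
      measurement = m,
      interval = c("baseline_to_week6", "baseline_to_month6"),
      percent_change = c(percent_change(base, group_means["week6", m]),
                         percent_change(base, group_means["month6", m])))
    if (per_subject_change) {
      out$per_subject_mean <- vapply(c("week6", "month6"), function(tp) {
        wide <- merge(
          table[table$timepoint == "baseline", c("subject_id", m)],
          table[table$timepoint == tp, c("subject_id", m)],
          by = "subject_id")
        ok <- complete.cases(wide[, 2:3]) & wide[, 2L] > 0
        round(mean(100 * (wide[ok, 2L] - wide[ok, 3L]) / wide[ok, 2L]))
      }, numeric(1))
    }
    out
  }))

  agreement <- NULL
  if (all(c("manual_volume_mL", "semiauto_volume_mL") %in% meas)) {
    agreement <- icc_agreement(table$manual_volume_mL,
                               table$semiauto_volume_mL)
  }

  cor_vars <- intersect(c("max_thickness_mm", "length_cm",
                          "manual_volume_mL", "semiauto_volume_mL"), meas)
  r <- diag(1, length(cor_vars))
  dimnames(r) <- list(cor_vars, cor_vars)
  pairs <- list()
  if (length(cor_vars) >= 2L) {
    for (i in seq_along(cor_vars)[-length(cor_vars)]) {
      for (j in seq.int(i + 1L, length(cor_vars))) {
        pc_ij <- pearson_ci(table[[cor_vars[i]]], table[[cor_vars[j]]])
        r[i, j] <- r[j, i] <- pc_ij$r
        pairs[[paste(cor_vars[i], cor_vars[j], sep = " vs ")]] <- pc_ij
      }
    }
  }

  structure(list(change_tests = change_tests, percent_changes = pc,
                 agreement = agreement,
                 correlations = list(r = r, pairs = pairs),
                 group_means = group_means,
                 n_records = nrow(table),
                 n_subjects = length(unique(table$subject_id))),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("<study_analysis> %d subjects, %d records\n",
              x$n_subjects, x$n_records))
  cat("Change over time (mixed-effects joint timepoint test):\n")
  for (ct in x$change_tests) {
    cat(sprintf("  %-20s %s   p = %.4g\n", ct$measurement,
                paste(sprintf("%.1f", ct$means), collapse = " vs. "),
                ct$p_value))
  }
  cat("Percent change of the group mean from baseline:\n")
  pcw <- stats::reshape(x$percent_changes[, 1:3], direction = "wide",
                        idvar = "measurement", timevar = "interval")
  for (i in seq_len(nrow(pcw))) {
    cat(sprintf("  %-20s %d%% (6 weeks), %d%% (6 months)\n",
                pcw$measurement[i], pcw[i, 2L], pcw[i, 3L]))
  }
  if (!is.null(x$agreement)) {
    cat("Manual vs semi-automated volume: ")
    print(x$agreement)
  }
  invisible(x)
}

# Flatten a study_analysis into the CSV tables written by write_report().
study_analysis_tables <- function(x) {
  ct <- do.call(rbind, lapply(x$change_tests, function(t) {
    data.frame(measurement = t$measurement,
               t(as.data.frame(t$means)),
               p_value = t$p_value, n_subjects = t$n_subjects,
               n_obs = t$n_obs, row.names = NULL)
  }))
  agr <- if (is.null(x$agreement)) {
    data.frame(icc = numeric(), ci_low = numeric(), ci_high = numeric(),
               band = character(), n_pairs = integer())
  } else {
    with(x$agreement, data.frame(icc = icc, ci_low = ci_low,
                                 ci_high = ci_high, band = band,
                                 n_pairs = n_pairs))
  }
  cors <- do.call(rbind, lapply(names(x$correlations$pairs), function(nm) {
    p <- x$correlations$pairs[[nm]]
    data.frame(pair = nm, r = p$r, ci_low = p$ci_low, ci_high = p$ci_high,
               p_value = p$p_value, n_pairs = p$n_pairs)
  }))
  if (is.null(cors)) {
    cors <- data.frame(pair = character(), r = numeric(),
                       ci_low = numeric(), ci_high = numeric(),
                       p_value = numeric(), n_pairs = integer())
  }
  list(change_tests = ct, percent_changes = x$percent_changes,
       agreement = agr, correlations = cors)
}

#' Tukey box plots of measurements over time
#'
#' One box per timepoint (whiskers at 1.5 x IQR, outliers as points), for
#' each requested measurement.
#'
#' @param table a longitudinal table.
#' @param measurements measurement columns to plot.
#' @export
plot_cohort <- function(table, measurements = measurement_names()) {
  table <- as_longitudinal_table(table)
  measurements <- intersect(measurements, names(table))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(measurements)))
  on.exit(graphics::par(old))
  for (m in measurements) {
    graphics::boxplot(table[[m]] ~ table$timepoint, range = 1.5,
                      xlab = "timepoint", ylab = m, main = m)
  }
  invisible(NULL)
}
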