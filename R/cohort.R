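#' Cohort simulator defaults
#'
#' Study-condition defaults for [make_longitudinal_cohort()]:
#' per-measurement baseline group means and multiplicative per-timepoint
#' shrink factors mirroring the published group means of a 20-child ileal
#' Crohn disease cohort imaged at diagnosis, 6 weeks and 6 months of
#' anti-TNF therapy.
#'
#' @return A list with `baseline_means` (named vector) and
#'   `timepoint_effects` (named list of length-3 shrink-factor vectors).
#' @export
cohort_defaults <- function() {
  list(
    baseline_means = c(max_thickness_mm  = 7.6,
                       mean_thickness_mm = 3.6,
                       length_cm         = 19.2,
                       manual_volume_mL  = 19.8,
                       semiauto_volume_mL = 24.0),
    timepoint_effects = list(
      max_thickness_mm  = c(1, 5.8 / 7.6, 4.5 / 7.6),
      mean_thickness_mm = c(1, 3.3 / 3.6, 2.6 / 3.6),
      length_cm         = c(1, 12.2 / 19.2, 8.0 / 19.2),
      manual_volume_mL  = c(1, 11.6 / 19.8, 5.1 / 19.8),
      semiauto_volume_mL = c(1, 15.1 / 24.0, 9.1 / 24.0)))
}

measurement_names <- function() {
  c("max_thickness_mm", "mean_thickness_mm", "length_cm",
    "manual_volume_mL", "semiauto_volume_mL")
}

timepoint_levels <- function() c("baseline", "week6", "month6")

#' Simulate a longitudinal measurement cohort
#'
#' Generates per-subject, per-timepoint measurement records for the five
#' imaging biomarkers (maximum and mean wall thickness, length of
#' disease, manual and semi-automated wall volume) under a multiplicative
#' treatment-response model: on the log scale each measurement is the
#' product of a per-measurement baseline mean, a per-timepoint shrink
#' factor, a shared subject-level random severity intercept, and
#' within-subject noise.  The semi-automated volume is derived from the
#' manual volume of the same visit (times the method's mean ratio and an
#' agreement error term), so the two volumetric columns are correlated
#' the way two segmentations of the same bowel are.
#'
#' @param n_subjects number of subjects (>= 2; default 20).
#' @param timepoint_effects multiplicative shrink factors in `(0, 1]` per
#'   timepoint (baseline, week 6, month 6): a length-3 vector applied to
#'   every measurement, or a named list per measurement.  Default: the
#'   published group-mean ratios (see [cohort_defaults()]).
#' @param between_subject_sd sd of the shared subject intercept, log
#'   scale.  Default 0.55, matching the large between-child spread of
#'   volumetric disease burden (coefficients of variation near 65%).
#' @param within_subject_sd sd of visit-level noise, log scale (>= 0).
#' @param agreement_sd sd of the log-scale manual vs semi-automated
#'   disagreement (>= 0); drives the ICC between the two volume columns.
#' @param baseline_means named vector of baseline group means (units of
#'   each measurement).
#' @param missingness `"none"`, or `"study"` to mimic the study's
#'   incomplete follow-up: one subject with baseline only, two subjects
#'   missing the 6-month visit.
#' @param rng_seed integer seed.
#' @return A `data.frame` (class `longitudinal_table`) with columns
#'   `subject_id`, `timepoint`, and the five measurements; one row per
#'   attended visit.
#' @export
make_longitudinal_cohort <- function(n_subjects = 20,
                                     timepoint_effects = NULL,
                                     between_subject_sd = 0.55,
                                     within_subject_sd = 0.25,
                                     agreement_sd = 0.20,
                                     baseline_means = NULL,
                                     missingness = c("none", "study"),
                                     rng_seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stopf("`n_subjects` must be at least 2 for a longitudinal design")
  }
  n_subjects <- as.integer(n_subjects)
  if (between_subject_sd < 0 || within_subject_sd < 0 || agreement_sd < 0) {
    stopf("standard deviations must be nonnegative")
  }
  missingness <- match.arg(missingness)
  defs <- cohort_defaults()
  if (is.null(baseline_means)) baseline_means <- defs$baseline_means
  meas <- measurement_names()
  if (!all(meas %in% names(baseline_means))) {
    stopf("`baseline_means` must name all of: %s", paste(meas, collapse = ", "))
  }
  if (is.null(timepoint_effects)) {
    eff <- defs$timepoint_effects
  } else if (is.numeric(timepoint_effects)) {
    if (length(timepoint_effects) != 3L) {
      stopf("`timepoint_effects` must have one factor per timepoint")
    }
    eff <- stats::setNames(rep(list(as.numeric(timepoint_effects)), length(meas)),
                           meas)
  } else {
    eff <- timepoint_effects
    if (!all(meas %in% names(eff))) {
      stopf("`timepoint_effects` list must name all five measurements")
    }
  }
  for (m in meas) {
    if (any(eff[[m]] <= 0) || any(eff[[m]] > 1)) {
      stopf("shrink factors must lie in (0, 1]")
    }
  }

  tps <- timepoint_levels()
  with_seed(rng_seed, {
    b <- rnorm(n_subjects, 0, between_subject_sd)
    rows <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                        timepoint = tps, stringsAsFactors = FALSE)
    rows <- rows[order(rows$subject_id), , drop = FALSE]
    tp_idx <- match(rows$timepoint, tps)
    sub_idx <- match(rows$subject_id, sprintf("S%02d", seq_len(n_subjects)))
    for (m in setdiff(meas, "semiauto_volume_mL")) {
      mu <- log(baseline_means[[m]]) + log(eff[[m]][tp_idx]) + b[sub_idx]
      rows[[m]] <- exp(mu + rnorm(nrow(rows), 0, within_subject_sd))
    }
    # Semi-automated volume: manual volume of the same visit, rescaled by
    # the method's mean ratio at that timepoint, plus agreement noise.
    ratio <- baseline_means[["semiauto_volume_mL"]] *
      eff[["semiauto_volume_mL"]][tp_idx] /
      (baseline_means[["manual_volume_mL"]] *
         eff[["manual_volume_mL"]][tp_idx])
    rows[["semiauto_volume_mL"]] <- rows[["manual_volume_mL"]] * ratio *
      exp(rnorm(nrow(rows), 0, agreement_sd))

    if (missingness == "study" && n_subjects >= 3L) {
      drop <- (sub_idx == 1L & tp_idx > 1L) |
        (sub_idx %in% c(2L, 3L) & tp_idx == 3L)
      rows <- rows[!drop, , drop = FALSE]
    }
    rownames(rows) <- NULL
    rows$timepoint <- factor(rows$timepoint, levels = tps)
    as_longitudinal_table(rows)
  })
}

#' Validate a longitudinal measurement table
#'
#' Checks the cohort-table contract: a `subject_id` column, a `timepoint`
#' column with levels baseline / week6 / month6, unique
#' (subject, timepoint) pairs, and nonnegative measurement values
#' (missing values allowed — absent visits carry information in their
#' absence, never as zeros).
#'
#' @param table a data.frame of measurement records.
#' @return The table, with `timepoint` as a factor and class
#'   `longitudinal_table` prepended.
#' @export
as_longitudinal_table <- function(table) {
  if (!is.data.frame(table)) stopf("cohort table must be a data.frame")
  need <- c("subject_id", "timepoint")
  if (!all(need %in% names(table))) {
    stopf("cohort table must have columns: %s", paste(need, collapse = ", "))
  }
  if (!all(as.character(table$timepoint) %in% timepoint_levels())) {
    stopf("timepoint values must be among: %s",
          paste(timepoint_levels(), collapse = ", "))
  }
  table$timepoint <- factor(as.character(table$timepoint),
                            levels = timepoint_levels())
  key <- paste(table$subject_id, table$timepoint)
  if (anyDuplicated(key)) {
    stopf("duplicate (subject, timepoint) records: %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  for (m in intersect(measurement_names(), names(table))) {
    v <- table[[m]]
    if (!is.numeric(v)) stopf("measurement `%s` must be numeric", m)
    if (any(v < 0, na.rm = TRUE)) stopf("measurement `%s` has negative values", m)
  }
  class(table) <- unique(c("longitudinal_table", class(table)))
  table
}

#' Write cohort and statistics reports as CSV
#'
#' Writes the measurement table (deterministic column order) and, when
#' given, the full statistics bundle from [run_study_analysis()] as
#' separate CSV files: `cohort.csv`, `change_tests.csv`,
#' `percent_changes.csv`, `agreement.csv`, `correlations.csv`.
#'
#' @param table a longitudinal table (validated on entry).
#' @param results optional `study_analysis` object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(table, results = NULL, dir) {
  table <- as_longitudinal_table(table)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- c("subject_id", "timepoint",
            intersect(measurement_names(), names(table)))
  paths <- file.path(dir, "cohort.csv")
  write.csv(table[, cols, drop = FALSE], paths[1L], row.names = FALSE,
            na = "")
  if (!is.null(results)) {
    stopifnot(inherits(results, "study_analysis"))
    tabs <- study_analysis_tables(results)
    for (nm in names(tabs)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      write.csv(tabs[[nm]], p, row.names = FALSE, na = "")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
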