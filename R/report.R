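# Study-level aggregation: per-condition and overall summary tables,
# error-ratio aggregation under the two-thirds-of-max-ROM rule, and
# Bland-Altman agreement of per-trial ROM measurements.

#' Aggregate per-trial results into a study report
#'
#' Produces the study-level summary tables: per condition and per axis, the
#' mean and SD across subjects of actual/estimated ROM, RMS error and
#' Pearson r; overall rows both as pooled mean/SD across all subject-trials
#' and as the mean of condition means; the error-ratio summary restricted to
#' trials whose actual ROM exceeds two-thirds of that subject-axis's maximum
#' across trials; and a Bland-Altman analysis of per-trial ROM pairs
#' (estimated vs actual) per axis.
#'
#' @param trial_results Data frame as returned by [evaluate_trial()] (rows
#'   stacked over trials).
#' @param two_thirds_reference `"per_subject_max"` (default) compares each
#'   trial's ROM to the subject's max on that axis; a named numeric vector
#'   (per axis, degrees) uses a fixed reference ROM instead.
#' @return List of class `study_report`: `by_condition`, `overall`,
#'   `overall_mean_of_conditions`, `error_ratio`, `bland_altman` (per-axis
#'   list), `trial_results`.
#' @export
build_report <- function(trial_results,
                         two_thirds_reference = "per_subject_max") {
  tr <- trial_results
  need <- c("subject", "trial", "condition", "axis", "rom_actual_deg",
            "rom_est_deg", "rms_error_deg", "pearson_r")
  missing <- setdiff(need, names(tr))
  if (length(missing) || nrow(tr) == 0) {
    lum_error("trial results are empty or missing required columns",
              class = "lum_schema_error", columns = missing)
  }
  stats_cols <- c("rom_actual_deg", "rom_est_deg", "rms_error_deg", "pearson_r")
  agg <- function(df, by) {
    sp <- split(df, df[by], drop = TRUE)
    rows <- lapply(sp, function(g) {
      out <- g[1, by, drop = FALSE]
      for (cl in stats_cols) {
        out[[paste0(cl, "_mean")]] <- mean(g[[cl]], na.rm = TRUE)
        out[[paste0(cl, "_sd")]] <- stats::sd(g[[cl]][!is.na(g[[cl]])])
      }
      out$n <- nrow(g)
      out
    })
    r <- do.call(rbind, rows)
    rownames(r) <- NULL
    r
  }
  by_condition <- agg(tr, c("condition", "axis"))
  by_condition <- by_condition[order(match(by_condition$condition, CONDITION_IDS),
                                     match(by_condition$axis, AXES)), ]
  rownames(by_condition) <- NULL
  overall <- agg(tr, "axis")
  overall <- overall[match(AXES, overall$axis), ]
  rownames(overall) <- NULL

  momc <- do.call(rbind, lapply(AXES, function(a) {
    g <- by_condition[by_condition$axis == a, ]
    data.frame(axis = a,
               rom_actual_deg_mean = mean(g$rom_actual_deg_mean),
               rom_est_deg_mean = mean(g$rom_est_deg_mean),
               rms_error_deg_mean = mean(g$rms_error_deg_mean),
               pearson_r_mean = mean(g$pearson_r_mean, na.rm = TRUE))
  }))

  # Two-thirds-of-max-ROM error-ratio rule
  tr$error_ratio_pct <- NA_real_
  for (a in AXES) {
    sel <- tr$axis == a
    if (identical(two_thirds_reference, "per_subject_max")) {
      maxrom <- tapply(tr$rom_actual_deg[sel], tr$subject[sel], max)
      thr <- (2 / 3) * maxrom[as.character(tr$subject[sel])]
    } else {
      thr <- rep((2 / 3) * two_thirds_reference[[a]], sum(sel))
    }
    keep <- sel & tr$rom_actual_deg > c(thr) & tr$rom_actual_deg > 0
    tr$error_ratio_pct[keep] <-
      error_ratio(tr$rms_error_deg[keep], tr$rom_actual_deg[keep])
  }
  er <- do.call(rbind, lapply(AXES, function(a) {
    v <- tr$error_ratio_pct[tr$axis == a]
    v <- v[!is.na(v)]
    data.frame(axis = a, mean_pct = mean(v), sd_pct = stats::sd(v),
               n_included = length(v))
  }))

  ba <- lapply(AXES, function(a) {
    g <- tr[tr$axis == a, ]
    bland_altman(g$rom_est_deg, g$rom_actual_deg)
  })
  names(ba) <- AXES

  structure(list(by_condition = by_condition, overall = overall,
                 overall_mean_of_conditions = momc, error_ratio = er,
                 bland_altman = ba, trial_results = tr),
            class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 3, ...) {
  cat("Study report (", length(unique(x$trial_results$subject)), " subjects, ",
      nrow(x$trial_results) / 3, " trials)\n", sep = "")
  cat("\nOverall (pooled across subject-trials):\n")
  print(format(x$overall, digits = digits), row.names = FALSE)
  cat("\nError ratio (trials with ROM > 2/3 of subject-axis max):\n")
  print(format(x$error_ratio, digits = digits), row.names = FALSE)
  cat("\nBland-Altman of per-trial ROM (estimated - actual):\n")
  for (a in AXES) print(x$bland_altman[[a]])
  cat("\nNote: Pearson p-values ignore within-trial autocorrelation.\n")
  invisible(x)
}

#' Simulate a study and evaluate the estimator end-to-end
#'
#' Convenience wrapper: [simulate_study()], then [run_pipeline()] on every
#' trial (calibrating per trial on its first 10 s), [evaluate_trial()] and
#' [build_report()].
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of simulated subjects.
#' @param ... Passed to [run_pipeline()] (filter settings, pairing, ...).
#' @return A `study_report`; trial pipeline results are attached as
#'   attribute `"pipelines"`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_study(sim_config(), n_subjects = 2)
#' rep$overall
#' }
run_study <- function(config = sim_config(), n_subjects = 6, ...) {
  trials <- simulate_study(config, n_subjects)
  results <- vector("list", length(trials))
  pipes <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    pr <- run_pipeline(tr$markers, tr$sensors, ...)
    pipes[[i]] <- pr
    results[[i]] <- evaluate_trial(pr$reference, pr$estimated,
                                   subject = tr$subject, trial = tr$trial,
                                   condition = tr$condition)
  }
  rep <- build_report(do.call(rbind, results))
  attr(rep, "pipelines") <- pipes
  rep
}
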