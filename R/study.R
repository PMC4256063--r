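#' Analyse a simulated study
#'
#' Runs the full group-level pipeline on a [run_experiment()] /
#' [simulate_study()] dataset:
#'
#' 1. Lapse rates: catch-trial error proportions are averaged across the
#'    two tasks within each speed condition, and doubled to estimate the
#'    generative lapse probability (a random guess is correct half the
#'    time).
#' 2. Catch screening: participants with [catch_screen()] or more errors
#'    on the catch trials of any single task are excluded.
#' 3. Lapse correction: measured thresholds are divided by the
#'    simulation-derived inflation factors in `lapse_table` (skipped when
#'    `NULL`).
#' 4. Equivalent-noise decomposition: sampling from the corrected MTN via
#'    [nsamp_from_mtn()], internal noise via [sigma_int_from()].
#' 5. Screening and transforms: [screen_and_transform()].
#' 6. Developmental trajectories per measure, with the speed-by-log-age
#'    interaction test ([fit_trajectory()]).
#' 7. Hierarchical stepwise regression of log coherence thresholds on log
#'    age, log sampling and log internal noise, per speed
#'    ([hierarchical_regression()]).
#' 8. Correlations ([en_mc_correlations()]) and fixation stability
#'    ([fixation_stability()]).
#'
#' The analysis is a pure function of the dataset and the lapse table:
#' rerunning it reproduces identical output.
#'
#' @param dataset A `cohort_dataset`.
#' @param lapse_table Optional [lapse_correction_build()] table.
#' @param alpha Significance level for the catch-trial binomial screen.
#' @param fixation_method Pooling rule for [fixation_stability()].
#' @return An object of class `study_analysis`: `estimates` (per
#'   participant-speed with corrected thresholds, `n_samp`, `sigma_int`),
#'   `screened` (the [screen_and_transform()] output), `trajectories`,
#'   `regressions` (one `regression_report` per speed), `correlations`,
#'   `fixation`, and `catch_criterion`.
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_per_group = 4, seed = 1)
#' ds <- run_experiment(generate_cohort(cfg), fixation = FALSE)
#' an <- analyze_study(ds)
#' an$trajectories
#' }
#' @export
analyze_study <- function(dataset, lapse_table = NULL, alpha = 0.05,
                          fixation_method = "rms") {
  stopifnot(inherits(dataset, "cohort_dataset"))
  est <- dataset$estimates

  rate <- (est$catch_errors_en / est$catch_trials_en +
             est$catch_errors_mc / est$catch_trials_mc) / 2
  est$lapse_rate <- rate
  est$lapse_hat <- pmin(2 * rate, 0.15)

  crit <- catch_screen(est$catch_trials_en[1], 0.5, alpha)
  fail <- est$catch_errors_en >= crit | est$catch_errors_mc >= crit
  failed_ids <- unique(est$participant_id[fail])
  catch_excluded <- est[est$participant_id %in% failed_ids, ]
  est <- est[!est$participant_id %in% failed_ids, ]

  ## participants whose coherence staircase railed at the 100% ceiling were
  ## unable to perform the task and are removed entirely
  ceiling_ids <- unique(est$participant_id[est$mc_threshold >= 0.995])
  ceiling_excluded <- est[est$participant_id %in% ceiling_ids, ]
  est <- est[!est$participant_id %in% ceiling_ids, ]

  if (!is.null(lapse_table)) {
    est$no_noise_threshold <- lapse_correct(est$no_noise_threshold,
                                            est$lapse_hat, lapse_table,
                                            "no_noise")
    est$mtn <- lapse_correct(est$mtn, est$lapse_hat, lapse_table,
                             "high_noise")
    est$mc_threshold <- lapse_correct(est$mc_threshold, est$lapse_hat,
                                      lapse_table, "coherence")
  }
  est$n_samp <- nsamp_from_mtn(est$mtn)
  est$sigma_int <- sigma_int_from(est$no_noise_threshold, est$n_samp)

  screened <- screen_and_transform(est)
  d <- screened$data
  d$log10_age <- log10(d$age_years)

  trajectories <- do.call(rbind, lapply(
    c("sigma_int", "n_samp", "mc_threshold"),
    function(m) {
      fit <- fit_trajectory(d[[paste0("log10_", m)]], d$log10_age,
                            d$speed_label, d$participant_id)
      ps <- fit$per_speed
      ps$measure <- m
      ps$interaction_estimate <- fit$interaction$estimate
      ps$interaction_p <- fit$interaction$p
      ps$speed_effect_p <- fit$speed_effect$p
      ps
    }
  ))

  regressions <- lapply(setNames(nm = unique(d$speed_label)), function(sp) {
    dd <- d[d$speed_label == sp, ]
    hierarchical_regression(dd)
  })

  correlations <- en_mc_correlations(d)

  fixation <- NULL
  if (!is.null(dataset$fixation)) {
    fixation <- fixation_stability(dataset$fixation,
                                   method = fixation_method)
  }

  structure(
    list(estimates = est, screened = screened, trajectories = trajectories,
         regressions = regressions, correlations = correlations,
         fixation = fixation, catch_criterion = crit,
         catch_excluded = catch_excluded,
         ceiling_excluded = ceiling_excluded),
    class = "study_analysis"
  )
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf(
    "Study analysis: %d estimate rows retained, %d participants excluded by catch screen (criterion %d errors)\n",
    nrow(x$screened$data), length(unique(x$catch_excluded$participant_id)),
    x$catch_criterion
  ))
  cat("Trajectory slopes (log10 measure vs log10 age):\n")
  print(x$trajectories[, c("measure", "speed_label", "slope",
                           "interaction_p")], digits = 3)
  invisible(x)
}

#' Write a study analysis to CSV reports
#'
#' Persists the screened estimates, exclusions, trajectory table,
#' regression coefficient tables (long format mirroring the
#' B / SE B / beta per step layout), correlations, moment tests and
#' fixation-stability table.
#'
#' @param analysis A `study_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "study_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      write.csv(x, file.path(out_dir, name), row.names = FALSE)
    }
  }
  w(analysis$screened$data, "screened_estimates.csv")
  w(analysis$screened$excluded, "excluded.csv")
  w(analysis$screened$moments, "moment_tests.csv")
  w(analysis$trajectories, "trajectory_report.csv")
  reg <- do.call(rbind, lapply(names(analysis$regressions), function(sp) {
    rep <- analysis$regressions[[sp]]
    do.call(rbind, lapply(names(rep$steps), function(st) {
      tab <- rep$steps[[st]]
      tab$speed_label <- sp
      tab$step <- st
      tab$r_squared <- unname(rep$r_squared[st])
      tab$delta_r_squared <- if (st == "step2") rep$delta_r_squared else NA
      tab
    }))
  }))
  w(reg, "regression_report.csv")
  w(analysis$correlations, "correlations.csv")
  w(analysis$fixation, "fixation_stability.csv")
  invisible(out_dir)
}
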