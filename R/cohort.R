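#' Configuration for a synthetic developmental cohort
#'
#' Defines the study structure the generator emulates: five age groups
#' (nominal 5, 7, 9 and 11 years and adults), two speed conditions (slow
#' 1.5 deg/s, fast 6 deg/s), and age trends in the generative observer
#' parameters. Each parameter is log-log-linear in age between an anchor at
#' the youngest group's mean age and an anchor at the adult mean age
#' (26.75 years): internal noise decreases with age (more steeply in the
#' fast condition), sampling increases, and lapse rate decreases.
#' Between-subject variability on log10 parameters is split into a
#' participant-level component shared across speeds and a speed-specific
#' component.
#'
#' @param n_per_group Participants per age group (scalar or length-5).
#' @param age_groups Group labels.
#' @param mean_ages Group mean ages in years.
#' @param age_jitter Half-width of the uniform age jitter per group, years.
#' @param sigma_int_anchors List with `slow` and `fast` length-2 vectors:
#'   internal noise (degrees) at the youngest and adult anchor ages.
#' @param nsamp_anchors Same structure for effective sampling.
#' @param lapse_anchors Same structure for the generative lapse probability.
#' @param between_sd_shared,between_sd_speed Between-subject SDs of log10
#'   internal noise and log10 sampling: shared-across-speed and
#'   speed-specific components (total SD is their root sum of squares).
#' @param lapse_log_sd Between-subject SD of log10 lapse.
#' @param coherence_seg_sd Between-subject log10 SD of the segmentation
#'   factor: a participant-level multiplier on the coherence observer's
#'   pooling noise capturing individual differences in segregating signal
#'   from noise dots, a limit specific to coherence stimuli. It decouples
#'   coherence thresholds from the equivalent-noise parameters beyond
#'   their systematic trends, as observed in human data where the
#'   sampling-coherence correlation is moderate rather than
#'   deterministic.
#' @param fixation_n_per_group Eyetracked participants per group.
#' @param fixation_sd_anchors Gaze SD (screen-normalised units) at the
#'   youngest and adult anchor ages.
#' @param fixation_trials,fixation_samples_per_trial Fixation trace sizes
#'   per task.
#' @param validity_probs Marginal probabilities of eyetracker validity
#'   codes 0-4.
#' @param seed Optional seed stored with the configuration and applied by
#'   [generate_cohort()] and [simulate_study()].
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_per_group = 4, seed = 1)
#' cfg$mean_ages
#' @export
cohort_config <- function(n_per_group = 25,
                          age_groups = c("5y", "7y", "9y", "11y", "adult"),
                          mean_ages = c(5.33, 7.25, 9.17, 11.25, 26.75),
                          age_jitter = c(0.5, 0.5, 0.5, 0.5, 4),
                          sigma_int_anchors = list(slow = c(9.62, 6.72),
                                                   fast = c(9.69, 4.80)),
                          nsamp_anchors = list(slow = c(0.51, 1.47),
                                               fast = c(0.98, 1.85)),
                          lapse_anchors = list(slow = c(0.045, 0.006),
                                               fast = c(0.035, 0.004)),
                          between_sd_shared = 0.12,
                          between_sd_speed = 0.10,
                          lapse_log_sd = 0.2,
                          coherence_seg_sd = 0.12,
                          fixation_n_per_group = c(12, 17, 11, 9, 10),
                          fixation_sd_anchors = c(0.12, 0.054),
                          fixation_trials = 20,
                          fixation_samples_per_trial = 16,
                          validity_probs = c(0.9, 0.05, 0.025, 0.015, 0.01),
                          seed = NULL) {
  k <- length(age_groups)
  stopifnot(length(mean_ages) == k, length(age_jitter) == k,
            all(mean_ages > 0), all(diff(mean_ages) > 0))
  n_per_group <- rep_len(as.integer(n_per_group), k)
  fixation_n_per_group <- pmin(rep_len(as.integer(fixation_n_per_group), k),
                               n_per_group)
  for (a in list(sigma_int_anchors, nsamp_anchors, lapse_anchors)) {
    stopifnot(is.list(a), all(c("slow", "fast") %in% names(a)),
              all(unlist(a) > 0))
  }
  stopifnot(abs(sum(validity_probs) - 1) < 1e-8, length(validity_probs) == 5)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(n_per_group = n_per_group, age_groups = age_groups,
         mean_ages = mean_ages, age_jitter = age_jitter,
         speeds = c(slow = 1.5, fast = 6),
         sigma_int_anchors = sigma_int_anchors,
         nsamp_anchors = nsamp_anchors, lapse_anchors = lapse_anchors,
         between_sd_shared = between_sd_shared,
         between_sd_speed = between_sd_speed, lapse_log_sd = lapse_log_sd,
         coherence_seg_sd = coherence_seg_sd,
         fixation_n_per_group = fixation_n_per_group,
         fixation_sd_anchors = fixation_sd_anchors,
         fixation_trials = as.integer(fixation_trials),
         fixation_samples_per_trial = as.integer(fixation_samples_per_trial),
         validity_probs = validity_probs, seed = seed),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config: %d participants in %d age groups x 2 speeds\n",
              sum(x$n_per_group), length(x$age_groups)))
  invisible(x)
}

#' @rdname cohort_config
#' @param config A `cohort_config`.
#' @param path File path for JSON round-tripping.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$sigma_int_anchors <- as.list(x$sigma_int_anchors)
  x$nsamp_anchors <- as.list(x$nsamp_anchors)
  x$lapse_anchors <- as.list(x$lapse_anchors)
  do.call(cohort_config, x[setdiff(names(x), "speeds")])
}

## log-log-linear interpolation between anchors at the youngest and adult
## mean ages; returns values on the linear scale. Equal (or zero) anchors
## degenerate to a flat trend.
anchor_interp <- function(age, anchors, anchor_ages) {
  if (anchors[1] == anchors[2] || anchors[1] <= 0) {
    return(rep(anchors[1], length(age)))
  }
  slope <- log10(anchors[2] / anchors[1]) /
    log10(anchor_ages[2] / anchor_ages[1])
  anchors[1] * (age / anchor_ages[1])^slope
}

#' Generate a synthetic developmental cohort
#'
#' Draws one observer-parameter triple per participant per speed condition
#' from the configured age trends: expected log10 internal noise falls
#' linearly with log10 age (more steeply for the fast speed), expected
#' log10 sampling rises, and lapse falls. Individual deviations combine a
#' participant-level component shared across speeds with a speed-specific
#' component.
#'
#' @param config A [cohort_config()].
#' @return A data frame of class `cohort` with one row per participant per
#'   speed: `participant_id`, `age_group`, `age_years`, `speed_label`,
#'   `speed`, `sigma_int`, `n_samp`, `lapse`. These are the generative
#'   (true) parameters, not estimates.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = 2, seed = 1))
#' head(cohort)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  anchor_ages <- config$mean_ages[c(1, length(config$mean_ages))]

  n_total <- sum(config$n_per_group)
  group <- rep(seq_along(config$age_groups), config$n_per_group)
  ages <- config$mean_ages[group] +
    runif(n_total, -config$age_jitter[group], config$age_jitter[group])
  z_shared_sig <- rnorm(n_total)
  z_shared_n <- rnorm(n_total)
  z_lapse <- rnorm(n_total)
  seg <- 10^(config$coherence_seg_sd * rnorm(n_total))

  per_speed <- lapply(c("slow", "fast"), function(sp) {
    sig <- anchor_interp(ages, config$sigma_int_anchors[[sp]],
                         anchor_ages) *
      10^(config$between_sd_shared * z_shared_sig +
            config$between_sd_speed * rnorm(n_total))
    nsm <- anchor_interp(ages, config$nsamp_anchors[[sp]], anchor_ages) *
      10^(config$between_sd_shared * z_shared_n +
            config$between_sd_speed * rnorm(n_total))
    lam <- anchor_interp(ages, config$lapse_anchors[[sp]], anchor_ages) *
      10^(config$lapse_log_sd * z_lapse)
    data.frame(
      participant_id = sprintf("P%03d", seq_len(n_total)),
      age_group = config$age_groups[group], age_years = ages,
      speed_label = sp, speed = unname(config$speeds[sp]),
      sigma_int = sig, n_samp = nsm,
      lapse = pmin(pmax(lam, 0), 0.25), seg_factor = seg
    )
  })
  out <- rbind(per_speed[[1]], per_speed[[2]])
  out <- out[order(out$participant_id, out$speed_label, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("cohort", "data.frame")
  out
}

#' Generate synthetic fixation traces
#'
#' Gaze samples at 40 Hz (25 ms intervals) during each stimulus interval.
#' Valid samples scatter around fixation with an age-dependent Gaussian SD
#' (younger children are less stable); samples carrying validity codes of 2
#' or higher are corrupted by large positional offsets, emulating
#' eye-not-found artefacts that downstream filtering must remove.
#'
#' @param age Participant age in years.
#' @param n_trials Number of stimulus intervals.
#' @param config A [cohort_config()] supplying the SD anchors, validity
#'   marginals and samples per trial.
#' @return Data frame with columns `trial`, `t_ms`, `x`, `y`, `val_l`,
#'   `val_r` (screen-normalised coordinates).
#' @examples
#' set.seed(1)
#' head(generate_fixation(5.3, n_trials = 2))
#' @export
generate_fixation <- function(age, n_trials, config = cohort_config()) {
  n_trials <- check_count(n_trials, "n_trials")
  anchor_ages <- config$mean_ages[c(1, length(config$mean_ages))]
  sd_age <- anchor_interp(age, config$fixation_sd_anchors, anchor_ages)
  spt <- config$fixation_samples_per_trial
  n <- n_trials * spt
  x <- rnorm(n, 0, sd_age)
  y <- rnorm(n, 0, sd_age)
  val_l <- sample(0:4, n, replace = TRUE, prob = config$validity_probs)
  val_r <- sample(0:4, n, replace = TRUE, prob = config$validity_probs)
  bad <- val_l >= 2 | val_r >= 2
  if (any(bad)) {
    k <- sum(bad)
    x[bad] <- x[bad] + sample(c(-1, 1), k, TRUE) * runif(k, 0.2, 0.5)
    y[bad] <- y[bad] + sample(c(-1, 1), k, TRUE) * runif(k, 0.2, 0.5)
  }
  data.frame(trial = rep(seq_len(n_trials), each = spt),
             t_ms = rep((seq_len(spt) - 1L) * 25L, n_trials),
             x = x, y = y, val_l = val_l, val_r = val_r)
}

#' Run the full simulated experiment for a cohort
#'
#' Each participant completes, in each speed condition, one equivalent-noise
#' task (two interleaved 75-trial staircases plus 15 catch trials) and one
#' motion-coherence task (75 staircase trials plus 15 catch trials), via
#' [run_task()]. Fixation traces are generated for the configured
#' eyetracked subset of each age group.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param seed Optional seed (defaults to the cohort configuration's seed
#'   plus one, so that cohort generation and the experiment draw from
#'   distinct but reproducible streams).
#' @param n_dots Dots per coherence stimulus.
#' @param fixation Logical: generate fixation traces?
#' @return An object of class `cohort_dataset`: a list with `trials`
#'   (trial-level log across all tasks), `estimates` (one row per
#'   participant per speed with measured thresholds, catch errors and the
#'   generative truth columns `true_sigma_int`, `true_n_samp`,
#'   `true_lapse`), `fixation` (traces, or `NULL`), `cohort` and `config`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_per_group = 2, seed = 1))
#' ds <- run_experiment(cohort, fixation = FALSE)
#' nrow(ds$trials) # participants x 2 speeds x (165 + 90)
#' }
#' @export
run_experiment <- function(cohort, seed = NULL, n_dots = 100,
                           fixation = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  config <- attr(cohort, "config")
  if (is.null(seed) && !is.null(config$seed)) seed <- config$seed + 1L
  if (!is.null(seed)) set.seed(seed)

  en_plan <- task_plan("equivalent_noise")
  mc_plan <- task_plan("coherence")

  ## choose the eyetracked subset: first k participants of each group
  fix_ids <- character(0)
  if (fixation) {
    for (g in seq_along(config$age_groups)) {
      ids <- unique(cohort$participant_id[
        cohort$age_group == config$age_groups[g]])
      fix_ids <- c(fix_ids, head(ids, config$fixation_n_per_group[g]))
    }
  }

  trials <- vector("list", nrow(cohort) * 2L)
  est <- vector("list", nrow(cohort))
  fix <- list()
  for (r in seq_len(nrow(cohort))) {
    row <- cohort[r, ]
    params <- observer_params(row$sigma_int, row$n_samp, row$lapse)
    seg <- if ("seg_factor" %in% names(row)) row$seg_factor else 1
    ## segmentation limits apply to the coherence task only: the pooling
    ## noise is scaled by seg, i.e. the effective sampling is n/seg^2
    params_mc <- observer_params(row$sigma_int, row$n_samp / seg^2,
                                 row$lapse)
    en <- run_task(en_plan, params, speed = row$speed,
                   participant_id = row$participant_id, n_dots = n_dots)
    mc <- run_task(mc_plan, params_mc, speed = row$speed,
                   participant_id = row$participant_id, n_dots = n_dots)
    trials[[2L * r - 1L]] <- en$trials
    trials[[2L * r]] <- mc$trials
    est[[r]] <- data.frame(
      participant_id = row$participant_id, age_group = row$age_group,
      age_years = row$age_years, speed_label = row$speed_label,
      speed = row$speed,
      no_noise_threshold = unname(en$thresholds["no_noise"]),
      mtn = unname(en$thresholds["high_noise"]),
      mc_threshold = unname(mc$thresholds["coherence"]),
      catch_errors_en = en$catch_errors, catch_errors_mc = mc$catch_errors,
      catch_trials_en = en_plan$catch_trials,
      catch_trials_mc = mc_plan$catch_trials,
      ## uncorrected decomposition; the analysis recomputes these after
      ## lapse correction
      n_samp = nsamp_from_mtn(unname(en$thresholds["high_noise"])),
      sigma_int = sigma_int_from(unname(en$thresholds["no_noise"]),
                                 nsamp_from_mtn(
                                   unname(en$thresholds["high_noise"]))),
      true_sigma_int = row$sigma_int, true_n_samp = row$n_samp,
      true_lapse = row$lapse,
      true_seg_factor = if ("seg_factor" %in% names(row)) {
        row$seg_factor
      } else {
        1
      }
    )
    if (fixation && row$participant_id %in% fix_ids) {
      for (task in c("equivalent_noise", "coherence")) {
        f <- generate_fixation(row$age_years, config$fixation_trials,
                               config)
        f <- cbind(participant_id = row$participant_id, task = task,
                   speed_label = row$speed_label, speed = row$speed, f)
        fix[[length(fix) + 1L]] <- f
      }
    }
  }

  structure(
    list(trials = do.call(rbind, trials), estimates = do.call(rbind, est),
         fixation = if (length(fix)) do.call(rbind, fix) else NULL,
         cohort = cohort, config = config),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "Cohort dataset: %d participants, %d trials, %d estimate rows\n",
    length(unique(x$estimates$participant_id)), nrow(x$trials),
    nrow(x$estimates)
  ))
  invisible(x)
}

#' Simulate a full study and persist it to disk
#'
#' Convenience wrapper: [generate_cohort()] then [run_experiment()], writing
#' the trial-level log, the participant-level estimates, the generative
#' cohort table and the fixation traces as CSV plus the configuration
#' (including seed) as JSON. Reruns with the same configuration and seed
#' produce byte-identical files.
#'
#' @param config A [cohort_config()]; give it a `seed` for reproducibility.
#' @param out_dir Output directory (created if needed).
#' @param fixation Logical: generate fixation traces?
#' @param n_dots Dots per coherence stimulus.
#' @return The `cohort_dataset`, invisibly.
#' @export
simulate_study <- function(config = cohort_config(), out_dir,
                           fixation = TRUE, n_dots = 100) {
  cohort <- generate_cohort(config)
  ds <- run_experiment(cohort, n_dots = n_dots, fixation = fixation)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(ds$trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
  write.csv(ds$estimates, file.path(out_dir, "estimates.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(cohort), file.path(out_dir, "cohort.csv"),
            row.names = FALSE)
  if (!is.null(ds$fixation)) {
    write.csv(ds$fixation, file.path(out_dir, "fixation.csv"),
              row.names = FALSE)
  }
  write_cohort_config(config, file.path(out_dir, "config.json"))
  invisible(ds)
}

#' Read a simulated study back from disk
#'
#' @param dir Directory written by [simulate_study()].
#' @return A `cohort_dataset`.
#' @export
read_study <- function(dir) {
  config <- read_cohort_config(file.path(dir, "config.json"))
  cohort <- read.csv(file.path(dir, "cohort.csv"))
  attr(cohort, "config") <- config
  class(cohort) <- c("cohort", "data.frame")
  fix_path <- file.path(dir, "fixation.csv")
  structure(
    list(trials = read.csv(file.path(dir, "trials.csv")),
         estimates = read.csv(file.path(dir, "estimates.csv")),
         fixation = if (file.exists(fix_path)) read.csv(fix_path) else NULL,
         cohort = cohort, config = config),
    class = "cohort_dataset"
  )
}
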