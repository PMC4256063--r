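## Staircase kind definitions. Intensity is the linear stimulus variable the
## staircase controls: direction offset (deg) for no-noise, direction SD
## (deg) for high-noise (mirrored: more noise = harder), coherence proportion
## for the coherence task. Start values and lattice ranges are package
## choices recorded here and in the methods vignette.
staircase_kinds <- list(
  no_noise = list(start = 20, range = c(0.1, 90), mirrored = FALSE),
  high_noise = list(start = 20, range = c(1, 150), mirrored = TRUE),
  coherence = list(start = 0.5, range = c(0.01, 1), mirrored = FALSE)
)

#' Plan a threshold-estimation task
#'
#' The equivalent-noise task interleaves two 75-trial QUEST staircases (a
#' no-noise staircase tracking the direction-offset threshold at zero
#' external noise, and a high-noise staircase tracking the maximum tolerable
#' direction SD at a +/-45 degree pedestal) with 15 randomly positioned
#' catch trials, giving 165 trials. The coherence task runs a single
#' 75-trial staircase on coherence plus 15 catch trials, giving 90 trials.
#' Catch trials use the criterion-phase stimuli: a 45 degree offset at zero
#' noise, or 100% coherence.
#'
#' @param task `"equivalent_noise"` or `"coherence"`.
#' @param staircase_trials Trials per staircase.
#' @param catch_trials Number of interleaved catch trials.
#' @param target Target proportion correct defining the threshold (0.84,
#'   the mean-plus-one-SD point of a cumulative normal).
#' @return An object of class `task_plan`.
#' @examples
#' task_plan("equivalent_noise")$n_trials # 165
#' task_plan("coherence")$n_trials        # 90
#' @export
task_plan <- function(task = c("equivalent_noise", "coherence"),
                      staircase_trials = 75, catch_trials = 15,
                      target = 0.84) {
  task <- match.arg(task)
  staircase_trials <- check_count(staircase_trials, "staircase_trials")
  catch_trials <- check_count(catch_trials, "catch_trials", min = 0L)
  check_number(target, "target", lower = 0.5, upper = 1,
               allow_equal = FALSE)
  staircases <- if (task == "equivalent_noise") {
    c("no_noise", "high_noise")
  } else {
    "coherence"
  }
  structure(
    list(task = task, staircases = staircases,
         staircase_trials = staircase_trials, catch_trials = catch_trials,
         target = target,
         n_trials = length(staircases) * staircase_trials + catch_trials),
    class = "task_plan"
  )
}

#' @export
print.task_plan <- function(x, ...) {
  cat(sprintf("Task plan '%s': %d x %d staircase trials + %d catch = %d\n",
              x$task, length(x$staircases), x$staircase_trials,
              x$catch_trials, x$n_trials))
  invisible(x)
}

## One simulated trial of a given staircase kind at linear intensity
## `intensity`, with the signal on side `side` (+1 right, -1 left).
## Returns the signed choice.
staircase_choice <- function(kind, params, intensity, side, n_dots) {
  if (kind == "no_noise") {
    en_decision_core(params, side * intensity, 0, 1L)$choice
  } else if (kind == "high_noise") {
    en_decision_core(params, side * 45, intensity, 1L)$choice
  } else {
    coherence_choice_batch(params, intensity, side * 90, n_dots, 1L)
  }
}

catch_choice <- function(task, params, side, n_dots) {
  if (task == "equivalent_noise") {
    en_decision_core(params, side * 45, 0, 1L)$choice
  } else {
    coherence_choice_batch(params, 1, side * 90, n_dots, 1L)
  }
}

#' Run a simulated threshold-estimation task
#'
#' Runs the full trial sequence of a [task_plan()] against a generative
#' observer: staircase trials are placed by QUEST at the posterior mean of
#' log10 intensity, catch trials occupy uniformly random positions in the
#' sequence, the two equivalent-noise staircases are randomly interleaved,
#' and the signal side is randomised on every trial.
#'
#' @param plan A `task_plan`.
#' @param params An [observer_params()] triple.
#' @param speed Speed label carried into the trial log (deg/s); not used by
#'   the simulation itself.
#' @param participant_id Identifier carried into the trial log.
#' @param n_dots Dots per coherence stimulus.
#' @return An object of class `task_result`: a list with `trials` (the
#'   trial-level log), `thresholds` (named vector of linear-scale threshold
#'   estimates at the plan's target proportion, clamped to the staircase
#'   lattice), `catch_errors` (number of incorrect catch responses),
#'   `lapse_rate` (catch error proportion) and `quests` (final staircase
#'   states).
#' @examples
#' set.seed(1)
#' res <- run_task(task_plan("equivalent_noise"), observer_params(6, 1.85))
#' nrow(res$trials)
#' res$thresholds
#' @export
run_task <- function(plan, params, speed = NA_real_,
                     participant_id = NA_character_, n_dots = 100) {
  stopifnot(inherits(plan, "task_plan"), inherits(params, "observer_params"))
  n_dots <- check_count(n_dots, "n_dots")

  quests <- lapply(plan$staircases, function(k) {
    cfg <- staircase_kinds[[k]]
    quest_new(start = cfg$start, range = cfg$range, mirrored = cfg$mirrored)
  })
  names(quests) <- plan$staircases

  n <- plan$n_trials
  is_catch <- rep(FALSE, n)
  if (plan$catch_trials > 0) {
    is_catch[sample.int(n, plan$catch_trials)] <- TRUE
  }
  order_labels <- sample(rep(plan$staircases, each = plan$staircase_trials))
  staircase_id <- rep(NA_character_, n)
  staircase_id[!is_catch] <- order_labels

  intensity <- numeric(n)
  side <- sample(c(-1L, 1L), n, replace = TRUE)
  choice <- integer(n)
  for (i in seq_len(n)) {
    if (is_catch[i]) {
      intensity[i] <- if (plan$task == "equivalent_noise") 45 else 1
      choice[i] <- catch_choice(plan$task, params, side[i], n_dots)
    } else {
      k <- staircase_id[i]
      x <- quest_next(quests[[k]])
      intensity[i] <- 10^x
      choice[i] <- staircase_choice(k, params, intensity[i], side[i], n_dots)
      quests[[k]] <- quest_update(quests[[k]], x, choice[i] == side[i])
    }
  }
  correct <- choice == side

  thresholds <- vapply(quests, function(q) {
    est <- quest_threshold(q, plan$target)
    min(max(est, 10^q$x[1]), 10^q$x[length(q$x)])
  }, numeric(1))
  catch_errors <- sum(!correct[is_catch])

  trials <- data.frame(
    participant_id = participant_id, task = plan$task, speed = speed,
    trial_index = seq_len(n), staircase_id = staircase_id,
    is_catch = is_catch, intensity = intensity,
    signal_side = ifelse(side > 0, "right", "left"),
    choice = ifelse(choice > 0, "right", "left"), correct = correct
  )

  structure(
    list(trials = trials, thresholds = thresholds,
         catch_errors = catch_errors,
         lapse_rate = if (plan$catch_trials > 0) {
           catch_errors / plan$catch_trials
         } else {
           NA_real_
         },
         quests = quests),
    class = "task_result"
  )
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("Task result (%s): %d trials, %d catch errors\n",
              x$trials$task[1], nrow(x$trials), x$catch_errors))
  cat("  thresholds:",
      paste(sprintf("%s = %.3g", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n")
  invisible(x)
}

## Single-staircase run used by the lapse-correction simulations; returns
## just the threshold estimate.
run_staircase <- function(kind, params, trials = 75, target = 0.84,
                          n_dots = 100) {
  cfg <- staircase_kinds[[kind]]
  q <- quest_new(start = cfg$start, range = cfg$range,
                 mirrored = cfg$mirrored)
  for (i in seq_len(trials)) {
    x <- quest_next(q)
    side <- if (runif(1) < 0.5) -1L else 1L
    ch <- staircase_choice(kind, params, 10^x, side, n_dots)
    q <- quest_update(q, x, ch == side)
  }
  est <- quest_threshold(q, target)
  min(max(est, 10^q$x[1]), 10^q$x[length(q$x)])
}
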