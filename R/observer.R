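#' Generative observer parameters
#'
#' The triple defining a simulated participant in one speed condition:
#' additive internal noise `sigma_int` (degrees; the precision limit on each
#' local direction estimate), effective number of samples `n_samp` (the
#' divisor of the equivalent-noise variance law; may be fractional, in which
#' case it acts as global multiplicative noise rather than a literal dot
#' count), and `lapse`, the probability of a stimulus-independent random
#' response.
#'
#' @param sigma_int Internal noise in degrees (`>= 0`).
#' @param n_samp Effective number of samples (`> 0`).
#' @param lapse Lapse probability in \[0, 1\].
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(sigma_int = 6, n_samp = 1.85, lapse = 0.02)
#' @export
observer_params <- function(sigma_int, n_samp, lapse = 0) {
  check_number(sigma_int, "sigma_int", lower = 0)
  check_number(n_samp, "n_samp", lower = 0, allow_equal = FALSE)
  check_number(lapse, "lapse", lower = 0, upper = 1)
  structure(list(sigma_int = sigma_int, n_samp = n_samp, lapse = lapse),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("Observer: sigma_int = %g deg, n_samp = %g, lapse = %g\n",
              x$sigma_int, x$n_samp, x$lapse))
  invisible(x)
}

#' @rdname observer_params
#' @param params An `observer_params` object.
#' @param path File path for JSON round-tripping.
#' @export
write_observer_params <- function(params, path) {
  stopifnot(inherits(params, "observer_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname observer_params
#' @export
read_observer_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  observer_params(x$sigma_int, x$n_samp, x$lapse)
}

## Internal vectorised decision core for the equivalent-noise observer.
## Returns +1 (right) / -1 (left) choices and the lapse flags.
en_decision_core <- function(params, mean_direction, external_sd, n) {
  s <- sqrt((params$sigma_int^2 + external_sd^2) / params$n_samp)
  d <- wrap_angle(mean_direction + rnorm(n) * s)
  choice <- ifelse(d > 0, 1L, -1L)
  lapsed <- if (params$lapse > 0) runif(n) < params$lapse else rep(FALSE, n)
  if (any(lapsed)) {
    k <- sum(lapsed)
    choice[lapsed] <- ifelse(runif(k) < 0.5, 1L, -1L)
  }
  list(choice = choice, lapsed = lapsed)
}

#' Equivalent-noise observer decision
#'
#' One (or several) left/right decisions about the mean direction of a
#' wrapped-normal dot field. With probability `lapse` the response is a
#' uniform random guess; otherwise an internal direction estimate is drawn
#' from a wrapped normal with mean `mean_direction` and standard deviation
#' `sqrt((sigma_int^2 + external_sd^2) / n_samp)`, and the observer reports
#' "right" iff the estimate is clockwise of vertical. By construction the
#' 84%-correct offset threshold of this observer equals the equivalent-noise
#' variance law `sqrt((sigma_int^2 + external_sd^2) / n_samp)`.
#'
#' @param params An [observer_params()] triple.
#' @param mean_direction Mean stimulus direction(s) in degrees; vectorised.
#' @param external_sd External direction noise SD in degrees (`>= 0`),
#'   recycled against `mean_direction`.
#' @return A data frame with columns `choice` (`"left"`/`"right"`) and
#'   `lapsed` (logical; simulation truth, not observable in a real
#'   experiment).
#' @examples
#' set.seed(1)
#' obs <- observer_params(6, 1, 0)
#' r <- en_decision(obs, mean_direction = rep(6, 1000), external_sd = 0)
#' mean(r$choice == "right") # about pnorm(1) = 0.84
#' @export
en_decision <- function(params, mean_direction, external_sd = 0) {
  stopifnot(inherits(params, "observer_params"))
  if (any(external_sd < 0)) stop_invalid("external_sd must be >= 0")
  n <- max(length(mean_direction), length(external_sd))
  mean_direction <- rep_len(mean_direction, n)
  external_sd <- rep_len(external_sd, n)
  core <- en_decision_core(params, mean_direction, external_sd, n)
  data.frame(choice = ifelse(core$choice > 0, "right", "left"),
             lapsed = core$lapsed)
}

## Internal batch simulator for the coherence observer: `trials` independent
## stimulus fields at one coherence level; returns the +1/-1 choices.
coherence_choice_batch <- function(params, coherence, signal_direction,
                                   n_dots, trials) {
  n_signal <- round(coherence * n_dots)
  dirs <- matrix(runif(trials * n_dots, -180, 180), nrow = trials)
  if (n_signal > 0) dirs[, seq_len(n_signal)] <- signal_direction
  noisy <- dirs + rnorm(trials * n_dots) * params$sigma_int
  rad <- noisy * pi / 180
  ms <- rowMeans(sin(rad))
  mc <- rowMeans(cos(rad))
  mu <- atan2(ms, mc) * 180 / pi
  rho <- pmax(sqrt(ms^2 + mc^2), 1e-12)
  s <- sqrt(-2 * log(rho)) * 180 / pi
  est <- wrap_angle(mu + rnorm(trials) * s / sqrt(params$n_samp))
  choice <- ifelse(est > 0, 1L, -1L)
  if (params$lapse > 0) {
    lapsed <- runif(trials) < params$lapse
    if (any(lapsed)) {
      choice[lapsed] <- ifelse(runif(sum(lapsed)) < 0.5, 1L, -1L)
    }
  }
  choice
}

#' Motion-coherence observer decision
#'
#' Decision model for the coherence task, for which no exact ideal observer
#' exists; the construction here is a pooling heuristic validated only by its
#' qualitative properties (thresholds fall with `n_samp`, rise with `lapse`).
#' Each dot direction is perturbed by independent Gaussian noise of SD
#' `sigma_int`; the circular mean of the perturbed dots is computed and then
#' perturbed once more by global noise with SD equal to the circular SD of
#' the perturbed dots divided by `sqrt(n_samp)`. The observer reports "right"
#' iff the resulting estimate is clockwise of vertical. Lapses are handled as
#' in [en_decision()].
#'
#' @param params An [observer_params()] triple.
#' @param field A coherence-dialect `direction_field` from
#'   [make_coherence_directions()].
#' @return A one-row data frame with columns `choice` and `lapsed`.
#' @examples
#' set.seed(1)
#' obs <- observer_params(6, 2, 0)
#' field <- make_coherence_directions(1, 90, 100)
#' coherence_decision(obs, field)$choice # "right"
#' @export
coherence_decision <- function(params, field) {
  stopifnot(inherits(params, "observer_params"),
            inherits(field, "direction_field"))
  if (is.null(field$coherence)) {
    stop_invalid("field must be a coherence-dialect direction field")
  }
  if (length(field$directions) == 0) stop_invalid("field is empty")
  if (params$lapse > 0 && runif(1) < params$lapse) {
    return(data.frame(choice = ifelse(runif(1) < 0.5, "right", "left"),
                      lapsed = TRUE))
  }
  noisy <- field$directions + rnorm(length(field$directions)) *
    params$sigma_int
  mu <- circ_mean(noisy)
  s <- circ_sd(noisy)
  est <- if (!is.finite(s)) {
    runif(1, -180, 180)
  } else {
    wrap_angle(mu + rnorm(1) * s / sqrt(params$n_samp))
  }
  data.frame(choice = ifelse(est > 0, "right", "left"), lapsed = FALSE)
}

#' Proportion correct of the dot-averaging ideal observer
#'
#' Monte Carlo estimate of the probability that an ideal observer averaging
#' `n_samples` dot directions reports the correct side of vertical. Each
#' sampled direction is drawn from a normal with mean `signal` and SD
#' `sqrt(external_sd^2 + sigma_int^2)` and the circular mean of the samples
#' is compared against vertical. This literal-averaging observer (rather
#' than the variance-scaling construction of [en_decision()]) is the model
#' behind the maximum-tolerable-noise mapping re-derivation: at large
#' direction SDs the circular mean loses information beyond what Gaussian
#' variance additivity predicts, which is exactly the regime the mapping
#' encodes.
#'
#' @param n_samples Integer number of directions averaged (`>= 1`).
#' @param external_sd External direction noise SD in degrees.
#' @param sigma_int Per-sample internal noise SD in degrees.
#' @param signal Signal direction in degrees (default +45, the high-noise
#'   task pedestal).
#' @param trials Number of Monte Carlo trials.
#' @return Estimated proportion correct.
#' @examples
#' set.seed(1)
#' average_observer_correct(1, external_sd = 45, trials = 2000) # about 0.84
#' @export
average_observer_correct <- function(n_samples, external_sd, sigma_int = 1,
                                     signal = 45, trials = 10000) {
  n_samples <- check_count(n_samples, "n_samples")
  check_number(external_sd, "external_sd", lower = 0)
  check_number(sigma_int, "sigma_int", lower = 0)
  sdev <- sqrt(external_sd^2 + sigma_int^2)
  th <- matrix((signal + rnorm(trials * n_samples) * sdev) * pi / 180,
               nrow = trials)
  m <- atan2(rowMeans(sin(th)), rowMeans(cos(th)))
  mean(sin(m) * sin(signal * pi / 180) > 0)
}

#' Monte Carlo thresholds of the generative observers
#'
#' `en_threshold_mc()` estimates the direction-offset threshold of the
#' equivalent-noise observer at a fixed external noise level by sweeping
#' offsets around the analytic prediction and interpolating the
#' target-proportion point on the probit scale. `coherence_threshold_mc()`
#' does the same for the coherence observer over coherence levels. These are
#' simulation oracles: they measure the observers' psychometric behaviour
#' directly, independently of any staircase.
#'
#' @param params An [observer_params()] triple.
#' @param external_sd External noise SD in degrees.
#' @param target Target proportion correct (default 0.84).
#' @param trials_per_level Monte Carlo trials per stimulus level.
#' @param n_levels Number of stimulus levels in the sweep.
#' @param span_octaves Half-width of the sweep around the analytic
#'   prediction, in octaves.
#' @param n_dots Dots per coherence stimulus.
#' @return The estimated threshold (degrees of direction offset, or a
#'   coherence proportion).
#' @examples
#' set.seed(1)
#' obs <- observer_params(6, 1, 0)
#' en_threshold_mc(obs, trials_per_level = 2000) # about 6 degrees
#' @export
en_threshold_mc <- function(params, external_sd = 0, target = 0.84,
                            trials_per_level = 8000, n_levels = 13,
                            span_octaves = 1.6) {
  pred <- sqrt((params$sigma_int^2 + external_sd^2) / params$n_samp)
  levels <- pred * 2^seq(-span_octaves, span_octaves, length.out = n_levels)
  p <- vapply(levels, function(m) {
    core <- en_decision_core(params, rep(m, trials_per_level),
                             rep(external_sd, trials_per_level),
                             trials_per_level)
    mean(core$choice > 0)
  }, numeric(1))
  interpolate_threshold(levels, p, target)
}

## Shared helper: given intensities and estimated proportions correct
## (increasing in intensity), return the intensity at `target` proportion by
## linear interpolation of the probit-transformed, monotonised curve.
interpolate_threshold <- function(levels, p, target) {
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  p <- cummax(p)  # enforce monotone non-decreasing
  z <- qnorm(p)
  zt <- qnorm(target)
  if (zt <= z[1]) return(levels[1])
  if (zt >= z[length(z)]) return(levels[length(levels)])
  i <- max(which(z < zt))
  l1 <- log(levels[i]); l2 <- log(levels[i + 1])
  exp(l1 + (zt - z[i]) / (z[i + 1] - z[i]) * (l2 - l1))
}

#' @rdname en_threshold_mc
#' @export
coherence_threshold_mc <- function(params, target = 0.84, n_dots = 100,
                                   trials_per_level = 4000, n_levels = 11) {
  levels <- exp(seq(log(0.02), log(1), length.out = n_levels))
  p <- vapply(levels, function(co) {
    mean(coherence_choice_batch(params, co, 90, n_dots,
                                trials_per_level) > 0)
  }, numeric(1))
  interpolate_threshold(levels, p, target)
}
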