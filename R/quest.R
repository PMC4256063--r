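#' Create a QUEST Bayesian adaptive staircase
#'
#' Maintains a discretised posterior over log10 threshold, updated after each
#' trial with a Weibull psychometric likelihood and used to place the next
#' trial at the posterior mean (the more stable placement rule at short run
#' lengths). For tasks where performance falls as intensity rises (the
#' high-noise condition, where "intensity" is the direction SD), set
#' `mirrored = TRUE` to flip the psychometric function.
#'
#' The assumed two-alternative psychometric function at lattice offset
#' `x - t` (log10 units) is
#' `p = delta * gamma + (1 - delta) * (1 - (1 - gamma) * exp(-10^(beta * (x - t))))`,
#' i.e. guess rate `gamma = 0.5`, slope `beta = 3.5` and lapse allowance
#' `delta = 0.01` by default.
#'
#' @param start Initial threshold guess on the linear intensity scale.
#' @param range Numeric length-2: lattice limits on the linear scale.
#' @param prior_sd Prior SD in log10 units.
#' @param beta,gamma,delta Weibull psychometric parameters.
#' @param grain Lattice spacing in log10 units.
#' @param mirrored Logical: `TRUE` when higher intensity means worse
#'   performance.
#' @return An object of class `quest` holding the lattice, posterior and
#'   trial history.
#' @examples
#' q <- quest_new(start = 20, range = c(0.1, 90))
#' quest_next(q)
#' @export
quest_new <- function(start, range, prior_sd = 1, beta = 3.5, gamma = 0.5,
                      delta = 0.01, grain = 0.02, mirrored = FALSE) {
  check_number(start, "start", lower = 0, allow_equal = FALSE)
  stopifnot(length(range) == 2, range[1] > 0, range[2] > range[1])
  lo <- log10(range[1])
  hi <- log10(range[2])
  ## lattice covers the full range inclusively at (approximately) `grain`
  x <- seq(lo, hi, length.out = ceiling((hi - lo) / grain) + 1L)
  prior <- dnorm(x, mean = log10(start), sd = prior_sd)
  prior <- prior / sum(prior)
  structure(
    list(x = x, posterior = prior, beta = beta, gamma = gamma, delta = delta,
         grain = grain, mirrored = mirrored,
         intensities = numeric(0), responses = logical(0)),
    class = "quest"
  )
}

#' @export
print.quest <- function(x, ...) {
  cat(sprintf(
    "QUEST staircase (%s): %d trials, threshold estimate %.3g\n",
    if (x$mirrored) "mirrored" else "standard", length(x$intensities),
    quest_threshold(x)
  ))
  invisible(x)
}

## Weibull probability of a correct response at log-intensity `x` for each
## candidate threshold `t` (vectorised over `t`).
quest_p_correct <- function(state, x, t) {
  sgn <- if (state$mirrored) -1 else 1
  state$delta * state$gamma +
    (1 - state$delta) *
      (1 - (1 - state$gamma) * exp(-10^(state$beta * sgn * (x - t))))
}

#' Update a QUEST posterior with one trial
#'
#' Multiplies the posterior by the Weibull likelihood of the observed
#' response at the tested intensity and renormalises. Intensities outside the
#' lattice range are clamped with a warning.
#'
#' @param state A `quest` object.
#' @param intensity Tested intensity in log10 units.
#' @param correct Logical: was the response correct?
#' @return The updated `quest` object.
#' @export
quest_update <- function(state, intensity, correct) {
  stopifnot(inherits(state, "quest"), is.logical(correct),
            length(correct) == 1)
  lo <- state$x[1]; hi <- state$x[length(state$x)]
  if (intensity < lo || intensity > hi) {
    warning("intensity ", format(intensity),
            " outside lattice range; clamped")
    intensity <- min(max(intensity, lo), hi)
  }
  p <- quest_p_correct(state, intensity, state$x)
  like <- if (correct) p else 1 - p
  post <- state$posterior * like
  total <- sum(post)
  if (total <= 0 || !is.finite(total)) {
    stop("QUEST posterior degenerated; check the lattice range")
  }
  state$posterior <- post / total
  state$intensities <- c(state$intensities, intensity)
  state$responses <- c(state$responses, correct)
  state
}

#' Trial history of a QUEST staircase
#'
#' @param state A `quest` object.
#' @return Data frame with one row per update: `intensity` (log10 units) and
#'   `correct`.
#' @export
quest_history <- function(state) {
  stopifnot(inherits(state, "quest"))
  data.frame(intensity = state$intensities, correct = state$responses)
}

#' QUEST posterior summaries and trial placement
#'
#' `quest_next()` returns the posterior mean of log10 threshold (the
#' placement for the next trial), `quest_mean()` and `quest_sd()` the
#' posterior mean and SD, `quest_quantile()` a posterior quantile, and
#' `quest_threshold()` the threshold on the linear scale read at a given
#' proportion correct of the assumed psychometric function (default 0.84,
#' the criterion level of the two-alternative design: the cumulative normal
#' at one SD above the mean).
#'
#' @param state A `quest` object.
#' @param prob Quantile level, or target proportion correct for
#'   `quest_threshold()`.
#' @return A numeric scalar (log10 units, except `quest_threshold()`, which
#'   is on the linear intensity scale).
#' @export
quest_next <- function(state) {
  stopifnot(inherits(state, "quest"))
  sum(state$x * state$posterior)
}

#' @rdname quest_next
#' @export
quest_mean <- quest_next

#' @rdname quest_next
#' @export
quest_sd <- function(state) {
  m <- quest_mean(state)
  sqrt(sum((state$x - m)^2 * state$posterior))
}

#' @rdname quest_next
#' @export
quest_quantile <- function(state, prob) {
  cdf <- cumsum(state$posterior)
  state$x[which(cdf >= prob)[1]]
}

#' @rdname quest_next
#' @export
quest_threshold <- function(state, prob = 0.84) {
  offset <- weibull_offset(prob, state$beta, state$gamma, state$delta)
  sgn <- if (state$mirrored) -1 else 1
  10^(quest_mean(state) + sgn * offset)
}

## log10 offset from the Weibull location parameter at which the assumed
## psychometric function reaches proportion `prob`.
weibull_offset <- function(prob, beta, gamma, delta) {
  q <- (1 - (prob - delta * gamma) / (1 - delta)) / (1 - gamma)
  if (q <= 0 || q >= 1) {
    stop_invalid("target proportion ", prob,
                 " is unreachable for the assumed psychometric function")
  }
  log10(-log(q)) / beta
}
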