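## The equivalent-noise decomposition. The variance law
##   sigma_obs^2 = (sigma_int^2 + sigma_ext^2) / n_samp
## links an observer's direction-discrimination threshold sigma_obs to
## additive internal noise sigma_int, external direction noise sigma_ext and
## the effective number of samples n_samp. The rapid two-point design
## measures (a) the threshold at zero external noise and (b) the maximum
## tolerable noise (MTN) at a 45-degree pedestal, and maps MTN to n_samp
## with a published quadratic-in-MTN transformation derived from ideal
## observer simulations.

#' Equivalent-noise threshold prediction
#'
#' Predicted 84%-correct direction threshold at a given external noise
#' level: `sqrt((sigma_int^2 + external_sd^2) / n_samp)`.
#'
#' @param sigma_int Internal noise in degrees.
#' @param n_samp Effective number of samples.
#' @param external_sd External direction noise SD in degrees (vectorised).
#' @return Predicted threshold(s) in degrees.
#' @examples
#' en_curve(6, 2, c(0, 6, 24))
#' @export
en_curve <- function(sigma_int, n_samp, external_sd) {
  check_number(sigma_int, "sigma_int", lower = 0)
  check_number(n_samp, "n_samp", lower = 0, allow_equal = FALSE)
  if (any(external_sd < 0)) stop_invalid("external_sd must be >= 0")
  sqrt((sigma_int^2 + external_sd^2) / n_samp)
}

#' Sampling from maximum tolerable noise
#'
#' The published mapping from the high-noise threshold (maximum tolerable
#' noise, MTN, in degrees of direction SD) to the effective number of
#' samples: `n_samp = exp(0.000121 * MTN^2 + 0.0357 * MTN - 1.8093)`.
#' Strictly increasing in MTN. See [rederive_mtn_mapping()] for a Monte
#' Carlo re-derivation of these coefficients.
#'
#' @param mtn Maximum tolerable noise in degrees (vectorised, `>= 0`).
#' @return Effective number of samples.
#' @examples
#' nsamp_from_mtn(45) # about 1.04: a 45-degree MTN is roughly one sample
#' @export
nsamp_from_mtn <- function(mtn) {
  if (!is.numeric(mtn) || any(!is.finite(mtn)) || any(mtn < 0)) {
    stop_invalid("mtn must be finite and >= 0")
  }
  exp(0.000121 * mtn^2 + 0.0357 * mtn - 1.8093)
}

#' Internal noise from the no-noise threshold and sampling
#'
#' At zero external noise the variance law reduces to
#' `sigma_int = threshold * sqrt(n_samp)`.
#'
#' @param no_noise_threshold 84%-correct offset threshold at zero external
#'   noise, in degrees (`> 0`).
#' @param n_samp Effective number of samples (`> 0`).
#' @return Internal noise in degrees.
#' @examples
#' sigma_int_from(4.41, 1.85) # about 6
#' @export
sigma_int_from <- function(no_noise_threshold, n_samp) {
  if (any(no_noise_threshold <= 0) || any(n_samp <= 0)) {
    stop_invalid("no_noise_threshold and n_samp must be positive")
  }
  no_noise_threshold * sqrt(n_samp)
}

#' Rapid two-point equivalent-noise estimates
#'
#' Combines the two measured thresholds into the four recovered quantities,
#' optionally correcting both thresholds for the observer's lapse rate
#' first: `n_samp` from the MTN via [nsamp_from_mtn()], then `sigma_int`
#' from the corrected no-noise threshold via [sigma_int_from()].
#'
#' @param no_noise_threshold Measured no-noise threshold in degrees.
#' @param mtn Measured maximum tolerable noise in degrees.
#' @param lapse Estimated generative lapse probability used for correction.
#' @param lapse_table Optional [lapse_correction_build()] table; if `NULL`
#'   no correction is applied.
#' @return A one-row data frame: `no_noise_threshold`, `mtn` (corrected
#'   values when a table is supplied), `n_samp`, `sigma_int`.
#' @export
en_estimates <- function(no_noise_threshold, mtn, lapse = 0,
                         lapse_table = NULL) {
  if (!is.null(lapse_table)) {
    no_noise_threshold <- lapse_correct(no_noise_threshold, lapse,
                                        lapse_table, "no_noise")
    mtn <- lapse_correct(mtn, lapse, lapse_table, "high_noise")
  }
  n_samp <- nsamp_from_mtn(mtn)
  data.frame(no_noise_threshold = no_noise_threshold, mtn = mtn,
             n_samp = n_samp,
             sigma_int = sigma_int_from(no_noise_threshold, n_samp))
}

#' Fit the full equivalent-noise function
#'
#' Least-squares fit of the variance law to thresholds measured at three or
#' more external noise levels, on log-threshold axes with equal weights.
#' This is the traditional multi-level analysis, used here as the oracle
#' against which the rapid two-point estimates are validated.
#'
#' @param external_sd External noise levels in degrees.
#' @param threshold Measured thresholds in degrees (same length).
#' @return A list with `sigma_int`, `n_samp`, the residual sum of squares
#'   `rss` (log space), and `fitted` thresholds.
#' @examples
#' sds <- c(0, 2, 4, 8, 16, 32)
#' fit_en_full(sds, en_curve(6, 2, sds))[c("sigma_int", "n_samp")]
#' @export
fit_en_full <- function(external_sd, threshold) {
  if (length(external_sd) != length(threshold)) {
    stop_invalid("external_sd and threshold must have equal length")
  }
  if (length(unique(external_sd)) < 3) {
    stop_invalid("need thresholds at >= 3 distinct external noise levels")
  }
  if (any(threshold <= 0)) stop_invalid("thresholds must be positive")
  obj <- function(par) {
    pred <- 0.5 * log((exp(2 * par[1]) + external_sd^2) / exp(par[2]))
    sum((log(threshold) - pred)^2)
  }
  ## start from the two-point logic: lowest-noise threshold and unit sampling
  start <- c(log(max(min(threshold), 1e-3)), 0)
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  sigma_int <- exp(fit$par[1])
  n_samp <- exp(fit$par[2])
  list(sigma_int = sigma_int, n_samp = n_samp, rss = fit$value,
       fitted = en_curve(sigma_int, n_samp, external_sd))
}

#' Re-derive the MTN-to-sampling mapping by Monte Carlo
#'
#' Simulates the high-noise task (+/-45 degree pedestal) for a grid of
#' sample counts using the dot-averaging ideal observer
#' ([average_observer_correct()]), finds each count's 84%-correct maximum
#' tolerable noise by probit interpolation of the simulated psychometric
#' function, and fits log sampling as a quadratic in MTN. The fitted
#' coefficients re-derive the published mapping of [nsamp_from_mtn()];
#' internal noise is set to a small positive value (1 degree) rather than
#' exactly zero to keep the simulation non-degenerate while honouring the
#' assumption that internal noise is negligible at high noise levels.
#'
#' @param nsamp_grid Integer sample counts to simulate.
#' @param sigma_int Per-sample internal noise in degrees.
#' @param trials_per_level Monte Carlo trials per noise level.
#' @param sd_levels External noise levels swept, in degrees.
#' @param target Target proportion correct (0.84).
#' @param signal Pedestal direction in degrees.
#' @return An object of class `mtn_mapping`: coefficients of the quadratic
#'   (`intercept`, `mtn`, `mtn_sq`), the simulated `mtn` per grid point,
#'   the `nsamp_grid`, and the fit's `r_squared`. Use `predict()` to map
#'   MTN values to sampling estimates.
#' @examples
#' \donttest{
#' set.seed(1)
#' map <- rederive_mtn_mapping(nsamp_grid = c(1, 2, 4),
#'                             trials_per_level = 2000)
#' predict(map, 45)
#' }
#' @export
rederive_mtn_mapping <- function(nsamp_grid = 1:16,
                                 sigma_int = 1, trials_per_level = 50000,
                                 sd_levels = exp(seq(log(10), log(150),
                                                     length.out = 25)),
                                 target = 0.84, signal = 45) {
  if (length(nsamp_grid) < 3) {
    stop_invalid("nsamp_grid needs >= 3 levels to fit a quadratic")
  }
  if (trials_per_level < 1000) {
    warning("fewer than 1000 trials per cell; MTN estimates will be noisy")
  }
  find_mtn <- function(n, levels, trials) {
    p <- vapply(levels, function(sdev) {
      average_observer_correct(n, sdev, sigma_int = sigma_int,
                               signal = signal, trials = trials)
    }, numeric(1))
    ## performance falls with noise; flip to reuse the increasing-curve
    ## interpolator (identical crossing on the probit scale)
    interpolate_threshold(levels, 1 - p, 1 - target)
  }
  mtn <- vapply(nsamp_grid, function(n) {
    ## coarse sweep over the full range, then a refined sweep around the
    ## first crossing: the quadratic refit is sensitive to MTN noise at the
    ## ends of the grid, so precision matters more than span here. Small
    ## sample counts are cheap to simulate and carry the most leverage for
    ## the low-MTN extrapolation, so their trial counts are scaled up.
    trials <- trials_per_level * min(8, ceiling(8 / n))
    coarse <- find_mtn(n, sd_levels, max(2000, trials %/% 5))
    fine_levels <- coarse * 10^seq(-0.08, 0.08, length.out = 11)
    find_mtn(n, fine_levels, trials)
  }, numeric(1))
  fit <- lm(log(nsamp_grid) ~ mtn + I(mtn^2))
  coefs <- setNames(coef(fit), c("intercept", "mtn", "mtn_sq"))
  structure(
    list(coefficients = coefs, mtn = mtn, nsamp_grid = nsamp_grid,
         r_squared = summary(fit)$r.squared, sigma_int = sigma_int,
         trials_per_level = trials_per_level),
    class = "mtn_mapping"
  )
}

#' @export
predict.mtn_mapping <- function(object, mtn, ...) {
  co <- object$coefficients
  exp(co["intercept"] + co["mtn"] * mtn + co["mtn_sq"] * mtn^2)
}

#' @export
print.mtn_mapping <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "MTN -> n_samp mapping: log n = %.4g + %.4g*MTN + %.4g*MTN^2 (R2 = %.4f)\n",
    co["intercept"], co["mtn"], co["mtn_sq"], x$r_squared
  ))
  cat(sprintf("  simulated over n_samp in {%s}, sigma_int = %g deg\n",
              paste(x$nsamp_grid, collapse = ", "), x$sigma_int))
  invisible(x)
}

#' Build an ideal-observer lapse-correction table
#'
#' Staircase threshold estimates are biased when the observer lapses more
#' often than the staircase's assumed lapse allowance: offset and coherence
#' thresholds are inflated (factors above 1), while the mirrored high-noise
#' staircase under-estimates the maximum tolerable noise (factors below 1),
#' because a lapse at an easy low-noise level reads as evidence that less
#' noise is tolerable. This simulates, for each staircase kind and each
#' lapse rate on a grid, the median threshold of an otherwise identical
#' observer with and without lapses, and stores the multiplicative bias
#' factor. Factors are monotonised (isotonic regression, in the direction
#' the task implies) and the zero-lapse factor is exactly 1, so correction
#' at lapse 0 is the identity. [lapse_correct()] divides a measured
#' threshold by the factor interpolated at the observer's lapse rate.
#'
#' Lapse rates here are generative lapse probabilities (the probability of
#' a random response). A catch-trial error proportion estimates half the
#' generative rate, because a random guess is correct half the time;
#' multiply catch error proportions by 2 before looking up the table.
#'
#' @param lapse_grid Generative lapse probabilities covering \[0, 0.15\];
#'   the first entry must be 0.
#' @param base_params Observer used for the simulations (its `lapse` is
#'   overridden).
#' @param n_rep Simulated runs per grid cell.
#' @param tasks Staircase kinds to tabulate.
#' @param n_dots Dots per coherence stimulus.
#' @return An object of class `lapse_table`: a data frame with columns
#'   `task`, `lapse`, `factor`.
#' @examples
#' \donttest{
#' set.seed(1)
#' tab <- lapse_correction_build(n_rep = 10)
#' lapse_correct(10, 0.04, tab, "no_noise")
#' }
#' @export
lapse_correction_build <- function(lapse_grid = seq(0, 0.15, by = 0.025),
                                   base_params = observer_params(6, 1, 0),
                                   n_rep = 40,
                                   tasks = c("no_noise", "high_noise",
                                             "coherence"),
                                   n_dots = 100) {
  if (lapse_grid[1] != 0 || is.unsorted(lapse_grid)) {
    stop_invalid("lapse_grid must be sorted and start at 0")
  }
  rows <- lapply(tasks, function(task) {
    med <- vapply(lapse_grid, function(lam) {
      p <- observer_params(base_params$sigma_int, base_params$n_samp, lam)
      median(vapply(seq_len(n_rep), function(i) {
        run_staircase(task, p, n_dots = n_dots)
      }, numeric(1)))
    }, numeric(1))
    factor <- med / med[1]
    mirrored <- isTRUE(staircase_kinds[[task]]$mirrored)
    factor <- if (mirrored) {
      pmin(-isoreg(lapse_grid, -factor)$yf, 1)
    } else {
      pmax(isoreg(lapse_grid, factor)$yf, 1)
    }
    factor[1] <- 1
    data.frame(task = task, lapse = lapse_grid, factor = factor)
  })
  structure(do.call(rbind, rows), class = c("lapse_table", "data.frame"))
}

#' Correct thresholds for lapse-rate inflation
#'
#' @param threshold Measured threshold(s).
#' @param lapse Generative lapse probability estimate(s); values outside the
#'   table's grid are clamped with a warning.
#' @param table A `lapse_table` from [lapse_correction_build()].
#' @param task Staircase kind the threshold came from (`"no_noise"`,
#'   `"high_noise"` or `"coherence"`).
#' @return Corrected threshold(s): `threshold / factor(lapse)`.
#' @export
lapse_correct <- function(threshold, lapse, table, task) {
  stopifnot(inherits(table, "lapse_table"))
  tab <- table[table$task == task, ]
  if (nrow(tab) == 0) stop_invalid("no lapse table entries for task ", task)
  rng <- range(tab$lapse)
  if (any(lapse < rng[1] - 1e-12) || any(lapse > rng[2] + 1e-12)) {
    warning("lapse outside the correction grid; clamped to [",
            rng[1], ", ", rng[2], "]")
    lapse <- pmin(pmax(lapse, rng[1]), rng[2])
  }
  factor <- approx(tab$lapse, tab$factor, xout = lapse, rule = 2)$y
  threshold / factor
}

#' @rdname lapse_correction_build
#' @param table A `lapse_table`.
#' @param path File path for JSON serialisation.
#' @export
write_lapse_table <- function(table, path) {
  stopifnot(inherits(table, "lapse_table"))
  jsonlite::write_json(as.data.frame(table), path, digits = NA)
  invisible(path)
}

#' @rdname lapse_correction_build
#' @export
read_lapse_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(x), class = c("lapse_table", "data.frame"))
}
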