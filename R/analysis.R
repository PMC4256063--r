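#' Catch-trial exclusion criterion
#'
#' Smallest number of incorrect catch responses at which a one-sided exact
#' binomial test of the remaining correct responses against chance fails to
#' reach significance. Participants with at least that many catch errors
#' cannot be shown to perform above chance and are excluded. With 15 catch
#' trials, chance 0.5 and alpha 0.05 the criterion is 4 errors: 12 of 15
#' correct is still significant (p = 576/32768) but 11 of 15 is not
#' (p = 1941/32768).
#'
#' @param n_catch Number of catch trials.
#' @param chance Chance proportion correct.
#' @param alpha Significance level.
#' @return Integer: the exclusion criterion (minimum disqualifying error
#'   count).
#' @examples
#' catch_screen(15, 0.5, 0.05) # 4
#' @export
catch_screen <- function(n_catch = 15, chance = 0.5, alpha = 0.05) {
  n_catch <- check_count(n_catch, "n_catch")
  check_number(chance, "chance", lower = 0, upper = 1, allow_equal = FALSE)
  check_number(alpha, "alpha", lower = 0, upper = 1, allow_equal = FALSE)
  for (k in 0:n_catch) {
    p <- binom.test(n_catch - k, n_catch, p = chance,
                    alternative = "greater")$p.value
    if (p >= alpha) {
      return(k)
    }
  }
  n_catch
}

## Moment-based skewness and excess kurtosis with standard-error z tests
## (normal-approximation tests on sqrt(b1) and b2).
moment_tests <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) {
    return(data.frame(n = n, skewness = NA_real_, z_skew = NA_real_,
                      p_skew = NA_real_, kurtosis = NA_real_,
                      z_kurt = NA_real_, p_kurt = NA_real_))
  }
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2 - 3
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se_kurt <- sqrt(24 * n * (n - 1)^2 /
                    ((n - 3) * (n - 2) * (n + 3) * (n + 5)))
  z_s <- skew / se_skew
  z_k <- kurt / se_kurt
  data.frame(n = n, skewness = skew, z_skew = z_s,
             p_skew = 2 * pnorm(-abs(z_s)), kurtosis = kurt,
             z_kurt = z_k, p_kurt = 2 * pnorm(-abs(z_k)))
}

#' Screen and log-transform participant-level estimates
#'
#' Implements the screening pipeline applied before group analysis: rows
#' with non-positive measures are excluded with a reason; all measures are
#' log10-transformed (skewness and kurtosis significance is reported for
#' raw and log scales per speed condition); and any row whose log value
#' lies more than `z_cut` standard deviations from its age-group-by-speed
#' mean on any measure is flagged and removed.
#'
#' @param estimates Data frame with columns `participant_id`, `age_group`,
#'   `speed_label` and the measure columns.
#' @param measures Character vector of measure column names to screen.
#' @param z_cut Outlier cut in z scores (default 3).
#' @return A list with `data` (retained rows plus `log10_<measure>`
#'   columns), `excluded` (rows removed, with `reason`), and `moments`
#'   (the skewness/kurtosis report).
#' @export
screen_and_transform <- function(estimates,
                                 measures = c("sigma_int", "n_samp",
                                              "mc_threshold"),
                                 z_cut = 3) {
  stopifnot(all(c("participant_id", "age_group", "speed_label")
                %in% names(estimates)),
            all(measures %in% names(estimates)))
  est <- estimates
  reason <- rep(NA_character_, nrow(est))
  for (m in measures) {
    bad <- !is.finite(est[[m]]) | est[[m]] <= 0
    reason[bad & is.na(reason)] <- paste0("non_positive_", m)
  }
  keep <- is.na(reason)
  excluded <- est[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  est <- est[keep, , drop = FALSE]

  moments <- do.call(rbind, lapply(measures, function(m) {
    do.call(rbind, lapply(unique(est$speed_label), function(sp) {
      x <- est[[m]][est$speed_label == sp]
      raw <- moment_tests(x)
      lg <- moment_tests(log10(x))
      cbind(data.frame(measure = m, speed_label = sp, scale = c("raw", "log10")),
            rbind(raw, lg))
    }))
  }))

  for (m in measures) {
    est[[paste0("log10_", m)]] <- log10(est[[m]])
  }

  out_reason <- rep(NA_character_, nrow(est))
  cell <- interaction(est$age_group, est$speed_label, drop = TRUE)
  for (m in measures) {
    lv <- est[[paste0("log10_", m)]]
    mu <- ave(lv, cell, FUN = mean)
    sdev <- ave(lv, cell, FUN = sd)
    z <- ifelse(sdev > 0, (lv - mu) / sdev, 0)
    flag <- abs(z) > z_cut
    out_reason[flag & is.na(out_reason)] <- paste0("outlier_", m)
  }
  if (any(!is.na(out_reason))) {
    out <- est[!is.na(out_reason), , drop = FALSE]
    out$reason <- out_reason[!is.na(out_reason)]
    out <- out[, c(names(estimates), "reason"), drop = FALSE]
    excluded <- rbind(excluded[, c(names(estimates), "reason"),
                               drop = FALSE], out)
    est <- est[is.na(out_reason), , drop = FALSE]
  } else if (nrow(excluded)) {
    excluded <- excluded[, c(names(estimates), "reason"), drop = FALSE]
  }

  list(data = est, excluded = excluded, moments = moments)
}

#' Developmental trajectory fits with a speed-by-age interaction test
#'
#' Fits per-speed ordinary least squares of a log10 measure on log10 age,
#' and tests the speed-by-log-age interaction on within-participant speed
#' differences (fast minus slow), which removes participant-level variance
#' shared across speeds. The speed main effect is assessed on the same
#' differences.
#'
#' @param log_value Log10 measure values.
#' @param log_age Log10 ages.
#' @param speed_label `"slow"`/`"fast"` per row.
#' @param participant Participant identifier per row.
#' @return An object of class `trajectory_fit`: `per_speed` (slope,
#'   intercept, SEs, p per speed), `interaction` (difference-slope
#'   estimate, SE, t, p), and `speed_effect` (mean fast-slow difference
#'   and its t test).
#' @export
fit_trajectory <- function(log_value, log_age, speed_label, participant) {
  stopifnot(length(log_value) == length(log_age),
            length(log_value) == length(speed_label),
            length(log_value) == length(participant))
  if (length(unique(log_age)) < 2) {
    stop_invalid("log_age is constant; cannot fit a trajectory")
  }
  per_speed <- do.call(rbind, lapply(unique(speed_label), function(sp) {
    i <- speed_label == sp
    fit <- lm(log_value[i] ~ log_age[i])
    co <- summary(fit)$coefficients
    data.frame(speed_label = sp, intercept = co[1, 1], slope = co[2, 1],
               se_slope = co[2, 2], p_slope = co[2, 4],
               r_squared = summary(fit)$r.squared)
  }))

  wide_ids <- intersect(participant[speed_label == "slow"],
                        participant[speed_label == "fast"])
  interaction <- speed_effect <- NULL
  if (length(wide_ids) >= 3) {
    i_slow <- match(wide_ids, ifelse(speed_label == "slow", participant, NA))
    i_fast <- match(wide_ids, ifelse(speed_label == "fast", participant, NA))
    diff <- log_value[i_fast] - log_value[i_slow]
    la <- log_age[i_fast]
    fit <- lm(diff ~ la)
    co <- summary(fit)$coefficients
    interaction <- list(estimate = co[2, 1], se = co[2, 2], t = co[2, 3],
                        p = co[2, 4])
    tt <- stats::t.test(diff)
    speed_effect <- list(mean_diff = unname(tt$estimate),
                         t = unname(tt$statistic), p = tt$p.value)
  }
  structure(list(per_speed = per_speed, interaction = interaction,
                 speed_effect = speed_effect),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  print(x$per_speed)
  if (!is.null(x$interaction)) {
    cat(sprintf("speed x log-age interaction: %.3f (p = %.3g)\n",
                x$interaction$estimate, x$interaction$p))
  }
  invisible(x)
}

std_beta <- function(fit, data, response) {
  co <- coef(fit)
  terms <- names(co)[-1]
  vapply(terms, function(tm) {
    co[tm] * sd(data[[tm]]) / sd(data[[response]])
  }, numeric(1))
}

#' Hierarchical stepwise regression on motion-coherence thresholds
#'
#' Step 1 regresses log10 coherence threshold on log10 age alone. Step 2
#' offers log10 sampling and log10 internal noise for stepwise entry
#' (p-to-enter 0.05, p-to-remove 0.10): candidates enter in order of
#' significance, and entered terms are dropped again if their p value
#' rises above the removal criterion. Reports unstandardised coefficients,
#' standard errors, standardised betas, R-squared and the step-2 R-squared
#' increment.
#'
#' @param data Data frame with columns `log10_mc_threshold`, `log10_age`,
#'   `log10_n_samp`, `log10_sigma_int`.
#' @param p_enter,p_remove Stepwise entry and removal criteria.
#' @return An object of class `regression_report`: `steps` (coefficient
#'   tables), `r_squared`, `delta_r_squared`, `entered`, `excluded`
#'   (candidate terms with their final p values), and `max_vif`.
#' @export
hierarchical_regression <- function(data, p_enter = 0.05, p_remove = 0.10) {
  need <- c("log10_mc_threshold", "log10_age", "log10_n_samp",
            "log10_sigma_int")
  stopifnot(all(need %in% names(data)))
  data <- data[complete.cases(data[, need]), need]
  if (nrow(data) < 10) stop_invalid("need at least 10 complete rows")

  response <- "log10_mc_threshold"
  base <- "log10_age"
  candidates <- c("log10_n_samp", "log10_sigma_int")

  fit_terms <- function(terms) {
    lm(stats::reformulate(terms, response = response), data = data)
  }
  term_p <- function(fit, term) {
    co <- summary(fit)$coefficients
    co[term, 4]
  }

  fit1 <- fit_terms(base)
  included <- character(0)
  repeat {
    changed <- FALSE
    remaining <- setdiff(candidates, included)
    if (length(remaining)) {
      ps <- vapply(remaining, function(tm) {
        term_p(fit_terms(c(base, included, tm)), tm)
      }, numeric(1))
      if (min(ps) < p_enter) {
        included <- c(included, remaining[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(included)) {
      fit <- fit_terms(c(base, included))
      ps <- vapply(included, function(tm) term_p(fit, tm), numeric(1))
      if (max(ps) > p_remove) {
        included <- setdiff(included, included[which.max(ps)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit2 <- fit_terms(c(base, included))

  step_table <- function(fit) {
    co <- summary(fit)$coefficients
    betas <- c(NA_real_, std_beta(fit, data, response))
    data.frame(term = rownames(co), B = co[, 1], SE_B = co[, 2],
               beta = betas, t = co[, 3], p = co[, 4],
               row.names = NULL)
  }
  r2 <- c(step1 = summary(fit1)$r.squared, step2 = summary(fit2)$r.squared)

  excluded <- setdiff(candidates, included)
  excluded_p <- vapply(excluded, function(tm) {
    term_p(fit_terms(c(base, included, tm)), tm)
  }, numeric(1))

  ## variance-inflation check on the final model
  max_vif <- NA_real_
  preds <- c(base, included)
  if (length(preds) > 1) {
    max_vif <- max(vapply(preds, function(tm) {
      r2x <- summary(lm(stats::reformulate(setdiff(preds, tm),
                                           response = tm),
                        data = data))$r.squared
      1 / (1 - min(r2x, 1 - 1e-12))
    }, numeric(1)))
  }

  structure(
    list(steps = list(step1 = step_table(fit1), step2 = step_table(fit2)),
         r_squared = r2, delta_r_squared = unname(r2[2] - r2[1]),
         entered = included,
         excluded = data.frame(term = excluded, p = unname(excluded_p)),
         max_vif = max_vif, n = nrow(data)),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat("Step 1 (log age):\n")
  print(x$steps$step1, digits = 3)
  cat(sprintf("  R2 = %.3f\n", x$r_squared[1]))
  cat("Step 2 (stepwise):\n")
  print(x$steps$step2, digits = 3)
  cat(sprintf("  R2 = %.3f, delta R2 = %.3f\n", x$r_squared[2],
              x$delta_r_squared))
  if (nrow(x$excluded)) {
    cat("  excluded:", paste(sprintf("%s (p = %.2g)", x$excluded$term,
                                     x$excluded$p), collapse = ", "), "\n")
  }
  if (is.finite(x$max_vif) && x$max_vif > 10) {
    cat(sprintf("  warning: collinearity (max VIF = %.1f)\n", x$max_vif))
  }
  invisible(x)
}

#' Correlations between equivalent-noise measures and coherence thresholds
#'
#' Pearson correlations on log10 values, per speed condition: internal
#' noise versus coherence threshold and sampling versus coherence
#' threshold.
#'
#' @param data Data frame with columns `speed_label`,
#'   `log10_sigma_int`, `log10_n_samp`, `log10_mc_threshold`.
#' @return Data frame with `speed_label`, `measure`, `r`, `df`, `p`
#'   (`r = NA` when a variable has zero variance).
#' @export
en_mc_correlations <- function(data) {
  need <- c("speed_label", "log10_sigma_int", "log10_n_samp",
            "log10_mc_threshold")
  stopifnot(all(need %in% names(data)))
  rows <- list()
  for (sp in unique(data$speed_label)) {
    d <- data[data$speed_label == sp, ]
    if (nrow(d) < 3) stop_invalid("need >= 3 rows per speed condition")
    for (m in c("log10_sigma_int", "log10_n_samp")) {
      if (sd(d[[m]]) == 0 || sd(d$log10_mc_threshold) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          speed_label = sp, measure = m, r = NA_real_, df = nrow(d) - 2L,
          p = NA_real_)
      } else {
        ct <- cor.test(d[[m]], d$log10_mc_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          speed_label = sp, measure = m, r = unname(ct$estimate),
          df = unname(ct$parameter), p = ct$p.value)
      }
    }
  }
  do.call(rbind, rows)
}

#' Fixation stability from gaze traces
#'
#' Discards samples with a validity code of 2 or higher in either eye,
#' then summarises each participant-task-speed cell by the pooled standard
#' deviation of gaze positions: the root mean of the x and y variances by
#' default (`"rms"`), or the arithmetic mean of the two SDs
#' (`"mean"`). The pooled SD is log10-transformed; cells with fewer than
#' two valid samples or zero spread are flagged.
#'
#' @param fixation Data frame with columns `participant_id`, `task`,
#'   `speed_label`, `x`, `y`, `val_l`, `val_r`.
#' @param method Pooling rule: `"rms"` (default) or `"mean"`.
#' @return Data frame with one row per participant-task-speed:
#'   `n_valid`, `pooled_sd`, `log10_pooled_sd`, `flagged`.
#' @export
fixation_stability <- function(fixation, method = c("rms", "mean")) {
  method <- match.arg(method)
  need <- c("participant_id", "task", "speed_label", "x", "y", "val_l",
            "val_r")
  stopifnot(all(need %in% names(fixation)))
  valid <- fixation$val_l < 2 & fixation$val_r < 2
  f <- fixation[valid, ]
  cells <- unique(data.frame(participant_id = fixation$participant_id,
                             task = fixation$task,
                             speed_label = fixation$speed_label))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    d <- f[f$participant_id == cells$participant_id[i] &
             f$task == cells$task[i] &
             f$speed_label == cells$speed_label[i], ]
    n <- nrow(d)
    if (n < 2) {
      return(cbind(cells[i, ], n_valid = n, pooled_sd = NA_real_,
                   log10_pooled_sd = NA_real_, flagged = TRUE))
    }
    sx <- sd(d$x); sy <- sd(d$y)
    pooled <- if (method == "rms") sqrt((sx^2 + sy^2) / 2) else (sx + sy) / 2
    if (pooled <= 0) {
      return(cbind(cells[i, ], n_valid = n, pooled_sd = pooled,
                   log10_pooled_sd = NA_real_, flagged = TRUE))
    }
    cbind(cells[i, ], n_valid = n, pooled_sd = pooled,
          log10_pooled_sd = log10(pooled), flagged = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
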