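test_that("the binomial catch screen matches exact tail enumeration", {
  expect_identical(catch_screen(15, 0.5, 0.05), 4L)

  ## exhaustive check against direct tail sums for a range of designs
  for (n in c(5, 10, 15, 20, 30)) {
    for (alpha in c(0.01, 0.05, 0.2)) {
      got <- catch_screen(n, 0.5, alpha)
      oracle <- NA_integer_
      for (k in 0:n) {
        if (oracle_binom_tail(n - k, n, 0.5) >= alpha) {
          oracle <- k
          break
        }
      }
      expect_identical(got, oracle)
    }
  }
  ## stricter alpha tolerates fewer errors
  expect_lte(catch_screen(15, 0.5, 0.01), catch_screen(15, 0.5, 0.05))
})

make_estimates <- function(n = 40, mu = 0.8, sdev = 0.1, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    age_group = "9y", speed_label = "slow",
    sigma_int = 10^rnorm(n, mu, sdev),
    n_samp = 10^rnorm(n, 0, sdev),
    mc_threshold = 10^rnorm(n, -0.4, sdev)
  )
}

test_that("outlier screening removes only values beyond three z scores", {
  est <- make_estimates()
  lv <- log10(est$sigma_int)
  ## spike one row to mean + 4 sd: removed; mean + 2.9 sd: retained
  est4 <- est
  est4$sigma_int[1] <- 10^(mean(lv[-1]) + 4.05 * sd(lv[-1]))
  out <- screen_and_transform(est4)
  expect_true("P01" %in% out$excluded$participant_id)
  expect_match(out$excluded$reason[out$excluded$participant_id == "P01"],
               "outlier_sigma_int")

  est29 <- est
  est29$sigma_int[1] <- 10^(mean(lv[-1]) + 2.5 * sd(lv[-1]))
  out <- screen_and_transform(est29)
  expect_false("P01" %in% out$excluded$participant_id)
  expect_equal(nrow(out$data), 40)
  expect_true(all(c("log10_sigma_int", "log10_n_samp",
                    "log10_mc_threshold") %in% names(out$data)))

  ## non-positive raw values are excluded with a reason, not logged
  bad <- est
  bad$n_samp[2] <- -0.5
  out <- screen_and_transform(bad)
  expect_match(out$excluded$reason[out$excluded$participant_id == "P02"],
               "non_positive_n_samp")
})

test_that("log transformation reduces the skewness the screen reports", {
  set.seed(61)
  est <- make_estimates(n = 120, sdev = 0.25)
  out <- screen_and_transform(est)
  m <- out$moments
  raw <- m[m$measure == "sigma_int" & m$scale == "raw", ]
  lg <- m[m$measure == "sigma_int" & m$scale == "log10", ]
  expect_gt(raw$skewness, 0)          # log-normal raw values skew right
  expect_lt(abs(lg$skewness), abs(raw$skewness))
})

test_that("trajectory fits recover known slopes and calibrate the interaction test", {
  ages <- rep(c(5.33, 7.25, 9.17, 11.25, 26.75), each = 25)
  la <- log10(ages)
  n <- length(ages)

  set.seed(62)
  mk <- function(slope_slow, slope_fast, noise = 0.1) {
    shared <- rnorm(n, 0, 0.1)
    data.frame(
      log_value = c(-0.2 + slope_slow * la + shared + rnorm(n, 0, noise),
                    -0.25 + slope_fast * la + shared + rnorm(n, 0, noise)),
      log_age = c(la, la),
      speed_label = rep(c("slow", "fast"), each = n),
      participant = rep(sprintf("P%03d", seq_len(n)), 2)
    )
  }

  d <- mk(-0.2, -0.45)
  fit <- fit_trajectory(d$log_value, d$log_age, d$speed_label,
                        d$participant)
  ps <- fit$per_speed
  got_slow <- ps$slope[ps$speed_label == "slow"]
  se_slow <- ps$se_slope[ps$speed_label == "slow"]
  expect_lt(abs(got_slow - (-0.2)), 2.5 * se_slow)
  expect_lt(fit$interaction$p, 0.05)
  expect_lt(fit$interaction$estimate, 0)

  ## equal generative slopes: rejection rate compatible with alpha
  set.seed(63)
  rejections <- replicate(200, {
    d0 <- mk(-0.3, -0.3)
    fit_trajectory(d0$log_value, d0$log_age, d0$speed_label,
                   d0$participant)$interaction$p < 0.05
  })
  expect_lt(mean(rejections), 0.10)
  expect_gt(mean(rejections), 0.005)

  expect_error(fit_trajectory(rnorm(10), rep(1, 10),
                              rep(c("slow", "fast"), 5),
                              rep(sprintf("P%d", 1:5), 2)),
               class = "eqnoise_invalid")
})

test_that("a steeper fast-speed noise trend is detectable on generator draws", {
  ## power at the study's sample size for the default generative contrast,
  ## measured on the parameters themselves (no staircase noise)
  set.seed(64)
  hits <- replicate(20, {
    cohort <- generate_cohort(cohort_config())
    fit <- fit_trajectory(log10(cohort$sigma_int),
                          log10(cohort$age_years), cohort$speed_label,
                          cohort$participant_id)
    fit$interaction$p < 0.05 && fit$interaction$estimate < 0
  })
  expect_gte(mean(hits), 0.80)
})

test_that("stepwise regression keeps sampling and drops internal noise when sampling drives difficulty", {
  ages <- rep(c(5.33, 7.25, 9.17, 11.25, 26.75), each = 25)
  la <- log10(ages)
  n <- length(ages)
  span <- log10(26.75 / 5.33)

  set.seed(65)
  picks <- replicate(20, {
    ln_t <- log10(0.51) + (log10(1.47 / 0.51) / span) * (la - log10(5.33)) +
      rnorm(n, 0, 0.16)
    ls_t <- log10(9.62) + (log10(6.72 / 9.62) / span) * (la - log10(5.33)) +
      rnorm(n, 0, 0.16)
    d <- data.frame(
      log10_mc_threshold = -0.62 * ln_t + rnorm(n, 0, 0.12),
      log10_age = la,
      log10_n_samp = ln_t + rnorm(n, 0, 0.1),
      log10_sigma_int = ls_t + rnorm(n, 0, 0.1)
    )
    rep <- hierarchical_regression(d)
    c("log10_n_samp" %in% rep$entered,
      !"log10_sigma_int" %in% rep$entered)
  })
  expect_gte(mean(picks[1, ]), 0.80)
  expect_gte(mean(picks[2, ]), 0.80)
})

test_that("regression reports are internally consistent", {
  set.seed(66)
  n <- 120
  la <- runif(n, 0.7, 1.45)
  d <- data.frame(
    log10_age = la,
    log10_n_samp = 0.5 * la + rnorm(n, 0, 0.15),
    log10_sigma_int = -0.3 * la + rnorm(n, 0, 0.15)
  )
  ## both candidates carry independent signal: both should enter
  d$log10_mc_threshold <- -0.4 * d$log10_n_samp +
    0.4 * d$log10_sigma_int + rnorm(n, 0, 0.05)
  rep <- hierarchical_regression(d)
  expect_setequal(rep$entered, c("log10_n_samp", "log10_sigma_int"))

  ## delta R2 is exactly the difference of step R2s, and the final model
  ## R2 equals a direct two-predictor fit regardless of entry order
  expect_equal(rep$delta_r_squared,
               unname(rep$r_squared[2] - rep$r_squared[1]),
               tolerance = 1e-12)
  direct <- summary(lm(log10_mc_threshold ~ log10_age + log10_n_samp +
                         log10_sigma_int, data = d))$r.squared
  expect_equal(unname(rep$r_squared[2]), direct, tolerance = 1e-12)

  ## standardised betas match B * sd(x) / sd(y)
  s2 <- rep$steps$step2
  b <- s2$B[s2$term == "log10_n_samp"]
  expect_equal(s2$beta[s2$term == "log10_n_samp"],
               b * sd(d$log10_n_samp) / sd(d$log10_mc_threshold),
               tolerance = 1e-12)

  ## with no age trend in the response, age is not significant
  set.seed(67)
  d0 <- d
  d0$log10_mc_threshold <- rnorm(n, -0.4, 0.1)
  rep0 <- hierarchical_regression(d0)
  expect_gt(rep0$steps$step1$p[2], 0.01)
})

test_that("correlation reports behave on perfect, null and generated data", {
  d <- data.frame(
    speed_label = "slow",
    log10_sigma_int = seq(0.5, 1, length.out = 20),
    log10_n_samp = seq(0.3, -0.3, length.out = 20),
    log10_mc_threshold = seq(-0.6, -0.1, length.out = 20)
  )
  out <- en_mc_correlations(d)
  expect_equal(out$r[out$measure == "log10_n_samp"], -1, tolerance = 1e-12)
  expect_equal(out$r[out$measure == "log10_sigma_int"], 1,
               tolerance = 1e-12)

  ## permuted pairing: correlations collapse and p is rarely significant
  set.seed(68)
  fp <- replicate(100, {
    d2 <- d
    d2$log10_mc_threshold <- sample(d2$log10_mc_threshold)
    en_mc_correlations(d2)$p[2] < 0.05
  })
  expect_lte(mean(fp), 0.12)

  ## on generator truth, sampling correlates negatively with coherence
  ## difficulty (computed analytically from the pooling model)
  cohort <- generate_cohort(cohort_config(seed = 9))
  d3 <- data.frame(
    speed_label = cohort$speed_label,
    log10_sigma_int = log10(cohort$sigma_int),
    log10_n_samp = log10(cohort$n_samp),
    log10_mc_threshold = log10(pmin(
      exp(-0.624 * cohort$n_samp / cohort$seg_factor^2), 1))
  )
  out3 <- en_mc_correlations(d3)
  expect_true(all(out3$r[out3$measure == "log10_n_samp"] < -0.3))

  ## zero-variance input is reported as NA rather than an error
  d4 <- d
  d4$log10_sigma_int <- 1
  expect_true(is.na(
    en_mc_correlations(d4)$r[out$measure == "log10_sigma_int"]))
})

test_that("fixation stability filters invalid samples and pools x/y spread", {
  set.seed(69)
  n <- 4000
  base <- data.frame(
    participant_id = "P1", task = "equivalent_noise", speed_label = "slow",
    x = rnorm(n, 0, 0.08), y = rnorm(n, 0, 0.08),
    val_l = 0, val_r = 0
  )
  out <- fixation_stability(base)
  expect_lt(abs(out$pooled_sd / 0.08 - 1), 0.05)
  expect_false(out$flagged)

  ## spiked invalid samples do not move the estimate at all
  spiked <- rbind(base, within(base[1:200, ], {
    x <- x + 5; y <- y - 5; val_l <- 4
  }))
  out2 <- fixation_stability(spiked)
  expect_equal(out2$pooled_sd, out$pooled_sd, tolerance = 1e-12)

  ## all samples at fixation: zero spread is flagged, log undefined
  still <- base
  still$x <- 0
  still$y <- 0
  out3 <- fixation_stability(still)
  expect_true(out3$flagged)
  expect_true(is.na(out3$log10_pooled_sd))

  ## rms versus arithmetic-mean pooling differ for anisotropic scatter
  aniso <- base
  aniso$y <- rnorm(n, 0, 0.02)
  rms <- fixation_stability(aniso, method = "rms")$pooled_sd
  avg <- fixation_stability(aniso, method = "mean")$pooled_sd
  expect_gt(rms, avg)
  expect_lt(abs(rms - sqrt((sd(aniso$x)^2 + sd(aniso$y)^2) / 2)), 1e-12)
})
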