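test_that("the MTN mapping and variance-law algebra evaluate exactly", {
  ## direct evaluation of the printed coefficients
  expect_equal(nsamp_from_mtn(0), exp(-1.8093), tolerance = 1e-12)
  expect_equal(nsamp_from_mtn(45),
               exp(0.000121 * 45^2 + 0.0357 * 45 - 1.8093),
               tolerance = 1e-12)
  expect_true(nsamp_from_mtn(60) > nsamp_from_mtn(45) &&
                nsamp_from_mtn(45) > nsamp_from_mtn(30))
  expect_error(nsamp_from_mtn(-1), class = "eqnoise_invalid")

  ## Eq-3 algebra: identity at unit sampling, exact round trips
  expect_equal(sigma_int_from(7.3, 1), 7.3)
  expect_equal(sigma_int_from(4.411, 1.85), 6, tolerance = 1e-3)
  for (s in c(2, 6, 11)) {
    for (n in c(0.4, 1, 3)) {
      expect_equal(sigma_int_from(en_curve(s, n, 0), n), s,
                   tolerance = 1e-12)
    }
  }
  expect_error(sigma_int_from(-1, 2), class = "eqnoise_invalid")

  ## asymptote: slope 1 on log-log axes at large external noise
  slope <- (log(en_curve(6, 2, 4000)) - log(en_curve(6, 2, 400))) /
    (log(4000) - log(400))
  expect_equal(slope, 1, tolerance = 1e-3)
  expect_true(all(diff(en_curve(6, 2, seq(0, 100, 5))) >= 0))
})

test_that("full-curve fits recover generative parameters", {
  sds <- c(0, 2, 4, 8, 16, 32)
  fit <- fit_en_full(sds, en_curve(6, 2, sds))
  expect_equal(fit$sigma_int, 6, tolerance = 1e-4)
  expect_equal(fit$n_samp, 2, tolerance = 1e-4)

  ## 20% multiplicative threshold noise: median recovery within 10%
  set.seed(501)
  rec <- replicate(500, {
    noisy <- en_curve(6, 2, sds) * exp(rnorm(6, 0, 0.2))
    f <- fit_en_full(sds, noisy)
    c(f$sigma_int, f$n_samp)
  })
  expect_lt(abs(median(rec[1, ]) / 6 - 1), 0.1)
  expect_lt(abs(median(rec[2, ]) / 2 - 1), 0.1)

  expect_error(fit_en_full(c(0, 0, 8), c(4, 4.1, 6)),
               class = "eqnoise_invalid")
})

test_that("rapid two-point estimates agree with full-curve fits", {
  set.seed(502)
  sds <- c(0, 4, 8, 16, 32, 64)
  grid <- expand.grid(sigma_int = c(4, 6, 8, 10),
                      n_samp = c(0.3, 0.6, 1, 2, 4))
  plan <- task_plan("equivalent_noise")
  est <- t(apply(grid, 1, function(g) {
    p <- obs(g["sigma_int"], g["n_samp"], 0)
    rapid <- run_task(plan, p)$thresholds
    two_point <- en_estimates(rapid["no_noise"], rapid["high_noise"])
    full_th <- vapply(sds, function(s) {
      en_threshold_mc(p, s, trials_per_level = 3000)
    }, numeric(1))
    full <- fit_en_full(sds, full_th)
    c(rapid_n = two_point$n_samp, full_n = full$n_samp)
  }))
  expect_gt(cor(log10(est[, "rapid_n"]), log10(est[, "full_n"])), 0.8)
})

test_that("the Monte Carlo re-derivation reproduces the published mapping's shape", {
  set.seed(503)
  map <- rederive_mtn_mapping(nsamp_grid = c(1, 2, 4, 8),
                              trials_per_level = 5000)
  ## MTN grows with sampling
  expect_true(all(diff(map$mtn) > 0))
  expect_gt(map$r_squared, 0.98)
  ## one effective sample tolerates noise near the root of the published
  ## quadratic (Eq-2 equals 1 near 44 deg)
  expect_gt(map$mtn[1], 41)
  expect_lt(map$mtn[1], 48)
  ## the refit agrees with the published mapping where it was simulated
  for (m in c(45, 60, 80)) {
    expect_lt(abs(predict(map, m) / nsamp_from_mtn(m) - 1), 0.15)
  }
})

test_that("thresholds at matched internal and external noise rise by sqrt(2)", {
  set.seed(504)
  th0 <- en_threshold_mc(obs(8, 1, 0), 0, trials_per_level = 8000)
  th1 <- en_threshold_mc(obs(8, 1, 0), 8, trials_per_level = 8000)
  expect_lt(abs(th1 / th0 - sqrt(2)), 0.06)
})

test_that("lapse correction is the identity at zero lapse and monotone along the grid", {
  set.seed(505)
  tab <- lapse_correction_build(lapse_grid = seq(0, 0.15, by = 0.05),
                                n_rep = 30)
  for (task in unique(tab$task)) {
    f <- tab$factor[tab$task == task]
    expect_identical(f[1], 1)
    if (task == "high_noise") {
      expect_true(all(diff(f) <= 0))
      expect_true(all(f <= 1))
    } else {
      expect_true(all(diff(f) >= 0))
      expect_true(all(f >= 1))
    }
  }
  expect_identical(lapse_correct(12.3, 0, tab, "no_noise"), 12.3)
  expect_warning(lapse_correct(10, 0.4, tab, "no_noise"), "clamped")

  path <- withr::local_tempfile(fileext = ".json")
  write_lapse_table(tab, path)
  tab2 <- read_lapse_table(path)
  expect_equal(tab2$factor, tab$factor)
})

test_that("lapse-corrected thresholds recover the lapse-free internal noise", {
  set.seed(506)
  tab <- lapse_correction_build(lapse_grid = seq(0, 0.15, by = 0.05),
                                n_rep = 50)
  plan <- task_plan("equivalent_noise")
  sig_of <- function(lapse, correct) {
    reps <- replicate(400, {
      th <- run_task(plan, obs(6, 1, lapse))$thresholds
      if (correct) {
        th["no_noise"] <- lapse_correct(th["no_noise"], lapse, tab,
                                        "no_noise")
        th["high_noise"] <- lapse_correct(th["high_noise"], lapse, tab,
                                          "high_noise")
      }
      log10(sigma_int_from(th["no_noise"],
                           nsamp_from_mtn(th["high_noise"])))
    })
    mean(reps)
  }
  clean <- sig_of(0, FALSE)
  corrected <- sig_of(0.04, TRUE)
  expect_lt(abs(corrected - clean), log10(1.05))
})
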