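test_that("the generative model reproduces its anchors exactly when noise is off", {
  cfg <- cohort_config(n_per_group = 3, age_jitter = rep(0, 5),
                       between_sd_shared = 0, between_sd_speed = 0,
                       lapse_log_sd = 0, coherence_seg_sd = 0, seed = 1)
  cohort <- generate_cohort(cfg)

  pick <- function(group, sp, col) {
    unique(cohort[[col]][cohort$age_group == group &
                           cohort$speed_label == sp])
  }
  ## youngest-group and adult means sit on the configured anchors
  expect_equal(pick("5y", "fast", "sigma_int"), 9.69)
  expect_equal(pick("5y", "slow", "sigma_int"), 9.62)
  expect_equal(pick("adult", "fast", "sigma_int"), 4.80)
  expect_equal(pick("adult", "slow", "sigma_int"), 6.72)
  expect_equal(pick("5y", "fast", "n_samp"), 0.98)
  expect_equal(pick("adult", "slow", "n_samp"), 1.47)

  ## zero between-subject SD: every group member shares the same triple
  expect_equal(nrow(unique(cohort[, c("age_group", "speed_label",
                                      "sigma_int", "n_samp", "lapse")])),
               10)

  ## internal noise falls and sampling rises monotonically with age
  for (sp in c("slow", "fast")) {
    sig <- vapply(cfg$age_groups, pick, numeric(1), sp = sp,
                  col = "sigma_int")
    nsm <- vapply(cfg$age_groups, pick, numeric(1), sp = sp,
                  col = "n_samp")
    expect_true(all(diff(sig) < 0))
    expect_true(all(diff(nsm) > 0))
  }
})

test_that("generative slopes are recovered from noise-free parameter draws", {
  cfg <- cohort_config(n_per_group = 200, between_sd_shared = 0,
                       between_sd_speed = 0, lapse_log_sd = 0,
                       coherence_seg_sd = 0, seed = 2)
  cohort <- generate_cohort(cfg)
  for (sp in c("slow", "fast")) {
    d <- cohort[cohort$speed_label == sp, ]
    anchors <- cfg$sigma_int_anchors[[sp]]
    want <- log10(anchors[2] / anchors[1]) / log10(26.75 / 5.33)
    got <- coef(lm(log10(d$sigma_int) ~ log10(d$age_years)))[2]
    expect_equal(unname(got), want, tolerance = 0.02)
  }
})

test_that("the simulated experiment produces the full trial bookkeeping", {
  cfg <- cohort_config(n_per_group = 2, seed = 3)
  ds <- run_experiment(generate_cohort(cfg), fixation = FALSE)
  n_participants <- sum(cfg$n_per_group)
  expect_equal(nrow(ds$trials), n_participants * 2 * (165 + 90))
  expect_equal(nrow(ds$estimates), n_participants * 2)
  expect_true(all(ds$estimates$mtn > 0 & ds$estimates$n_samp > 0))
  ## the decomposition identity holds on every row
  expect_equal(ds$estimates$sigma_int,
               ds$estimates$no_noise_threshold *
                 sqrt(ds$estimates$n_samp),
               tolerance = 1e-12)
})

test_that("recovered group averages preserve the developmental ordering", {
  cfg <- cohort_config(n_per_group = 10, seed = 4)
  ds <- run_experiment(generate_cohort(cfg), fixation = FALSE)
  est <- ds$estimates
  gm <- function(col, group, sp) {
    10^mean(log10(est[[col]][est$age_group == group &
                               est$speed_label == sp]))
  }
  for (sp in c("slow", "fast")) {
    expect_gt(gm("sigma_int", "5y", sp), gm("sigma_int", "adult", sp))
    expect_lt(gm("n_samp", "5y", sp), gm("n_samp", "adult", sp))
    expect_gt(gm("mc_threshold", "5y", sp), gm("mc_threshold", "adult", sp))
  }
})

test_that("fixation traces have the configured sampling and age structure", {
  cfg <- cohort_config(seed = 5)
  set.seed(50)
  f <- generate_fixation(9, n_trials = 4, config = cfg)
  expect_equal(nrow(f), 4 * cfg$fixation_samples_per_trial)
  expect_equal(unique(diff(f$t_ms[f$trial == 1])), 25)
  expect_true(all(f$val_l %in% 0:4 & f$val_r %in% 0:4))

  ## valid-sample scatter recovers the generative SD
  set.seed(51)
  big <- generate_fixation(9, n_trials = 650, config = cfg)
  ok <- big$val_l < 2 & big$val_r < 2
  target <- 0.12 * (9 / 5.33)^(log10(0.054 / 0.12) / log10(26.75 / 5.33))
  expect_lt(abs(sd(big$x[ok]) / target - 1), 0.05)

  ## younger children scatter more
  set.seed(52)
  young <- generate_fixation(5.33, 400, cfg)
  adult <- generate_fixation(26.75, 400, cfg)
  expect_gt(sd(young$x[young$val_l < 2 & young$val_r < 2]),
            sd(adult$x[adult$val_l < 2 & adult$val_r < 2]))

  ## zero-SD anchors collapse all valid samples onto fixation
  cfg0 <- cohort_config(fixation_sd_anchors = c(0, 0), seed = 6)
  set.seed(53)
  f0 <- generate_fixation(7, 5, cfg0)
  ok <- f0$val_l < 2 & f0$val_r < 2
  expect_true(all(f0$x[ok] == 0 & f0$y[ok] == 0))
})

test_that("simulation is byte-reproducible from config and seed", {
  cfg <- cohort_config(n_per_group = 2, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  d1 <- run_experiment(c1, fixation = FALSE)
  d2 <- run_experiment(c2, fixation = FALSE)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$estimates, d2$estimates)

  ## config JSON round trip preserves the generator
  path <- withr::local_tempfile(fileext = ".json")
  write_cohort_config(cfg, path)
  cfg2 <- read_cohort_config(path)
  expect_identical(generate_cohort(cfg2), c1)
})
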