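test_that("empty and invalid configurations are handled", {
  cfg <- sim_config(n_subjects = 0, seed = 1)
  empty <- simulate_cohort(cfg)
  expect_s3_class(empty, "subject_table")
  expect_identical(nrow(empty), 0L)
  expect_error(sim_config(n_subjects = 10, lambda_S = 1.5), "lambda_S")
  expect_error(sim_config(n_subjects = 10, attrition_monthly = 1.2),
               "attrition_monthly")
  expect_error(sim_config(n_subjects = -5), "n_subjects")
})

test_that("the same configuration and seed reproduce the cohort exactly", {
  cfg <- test_cfg(seed = 42, n_subjects = 400)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  expect_identical(attr(a, "scores"), attr(b, "scores"))
})

test_that("attrition reproduces the closed-form geometric retention", {
  # male-cohort attrition is calibrated so that (1 - a)^12 matches the
  # published month-12 retention 16,479 / 18,838
  cfg <- outcome_preset("physical_perpetration", calibrate = FALSE)
  subj <- simulate_cohort(cfg)
  frac12 <- mean(subj$last_observed_month >= 12)
  expect_equal(frac12, (1 - cfg$attrition_monthly)^12, tolerance = 0.01)
  expect_equal(frac12, 16479 / 18838, tolerance = 0.01)
})

test_that("weights are positive with mean one and clusters cover everyone", {
  cfg <- test_cfg(seed = 3, n_subjects = 1000)
  subj <- simulate_cohort(cfg)
  expect_true(all(subj$weight > 0))
  expect_equal(mean(subj$weight), 1, tolerance = 1e-12)
  expect_false(anyNA(subj$cluster_id))
  expect_gt(length(unique(subj$cluster_id)), 1)
})

test_that("score loadings drive the within-month correlation", {
  # perfect loadings: correlation 1 every month
  cfg1 <- sim_config(n_subjects = 200, cluster_size_range = c(50, 50),
                     weight_sd = 0, lambda_S = 1, lambda_A_start = 1,
                     lambda_A_end = 1, seed = 5)
  subj <- simulate_scores(simulate_cohort(cfg1), cfg1)
  arr <- expand_person_months(subj)
  cs <- within_month_correlations(arr)
  expect_true(all(abs(cs$r[!is.na(cs$r)] - 1) < 1e-10))

  # zero monthly loading: correlations near zero
  cfg0 <- test_cfg(seed = 6, n_subjects = 3000)
  cfg0$lambda_A_start <- 0; cfg0$lambda_A_end <- 0
  subj0 <- simulate_scores(simulate_cohort(cfg0), cfg0)
  cs0 <- within_month_correlations(expand_person_months(subj0))
  r0 <- cs0$r[!is.na(cs0$r) & cs0$n_subjects > 500]
  expect_true(all(abs(r0) < 4 / sqrt(500)))
})

test_that("victimization preset's correlation schedule has median near 0.26", {
  cfg <- outcome_preset("victimization", calibrate = FALSE)
  # closed-form oracle: corr_m = lambda_S * lambda_A(m); the pooled cell
  # carries the final loading
  lamA <- cfg$lambda_A_start +
    (pmin(0:35, 35) / 35) * (cfg$lambda_A_end - cfg$lambda_A_start)
  corr <- cfg$lambda_S * c(lamA, lamA[36])
  expect_lt(abs(unname(summarize_series(corr)["median"]) - 0.26), 0.05)
})

test_that("degenerate hazards give no events or immediate events", {
  cfg <- test_cfg(seed = 9, n_subjects = 150)
  cfg$alpha_base <- -40; cfg$training_offset <- 0
  subj <- simulate_study(cfg)
  expect_identical(sum(!is.na(subj$event_month)), 0L)
  cfg$alpha_base <- 40
  subj2 <- simulate_study(cfg)
  expect_true(all(subj2$event_month == 0L))
  expect_true(all(subj2$last_observed_month == 0L))
})

test_that("realized incidence matches the analytic expectation", {
  cfg <- test_cfg(seed = 11, n_subjects = 20000, alpha_base = -6)
  subj <- simulate_study(cfg)
  wev <- sum(subj$weight * !is.na(subj$event_month))
  wpy <- sum(subj$weight * (subj$last_observed_month + 1)) / 12
  realized <- 1000 * wev / wpy
  expected <- expected_incidence(cfg)
  # ~700 events: three relative standard errors
  expect_lt(abs(realized - expected) / expected, 3 / sqrt(wev) + 0.02)
})

test_that("intercept calibration is a monotone fixed point", {
  cfg <- test_cfg(seed = 13, n_subjects = 500)
  cur <- expected_incidence(cfg)
  same <- calibrate_intercepts(cfg, cur)
  expect_equal(same$alpha_base, cfg$alpha_base, tolerance = 1e-3)
  c1 <- calibrate_intercepts(cfg, 5)
  c2 <- calibrate_intercepts(cfg, 25)
  expect_gt(c2$alpha_base, c1$alpha_base)
  expect_error(calibrate_intercepts(cfg, 1000), "unattainable")
  expect_error(calibrate_intercepts(cfg, -1), "positive")
})

test_that("scores are marginally standardized by construction", {
  cfg <- test_cfg(seed = 17, n_subjects = 6000)
  subj <- simulate_scores(simulate_cohort(cfg), cfg)
  st <- score_table(subj)
  expect_lt(abs(mean(subj$static_score)), 4 / sqrt(6000))
  expect_lt(abs(stats::var(subj$static_score) - 1), 0.06)
  m0 <- st$score_A[st$month == 0]
  expect_lt(abs(mean(m0)), 4 / sqrt(length(m0)))
  expect_lt(abs(stats::var(m0) - 1), 0.06)
})

test_that("cohorts round-trip through the delimited writer", {
  cfg <- test_cfg(seed = 19, n_subjects = 80)
  subj <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_cohort(subj, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(subj), as.data.frame(back),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(subj, "scores")$score_A, attr(back, "scores")$score_A,
               tolerance = 1e-12)
})
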