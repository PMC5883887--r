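# a fabricated additive fit usable for prediction without estimation
fake_fit <- function(intercept, beta_A = 0, beta_S = 0) {
  structure(list(
    coefficients = c("(Intercept)" = intercept, A = beta_A, S = beta_S),
    spec = model_spec(terms = c("T", "A", "S")),
    dummy_months = integer(0), ref_month = 0L,
    term_cols = list(T = character(0), A = "A", S = "S")),
    class = "hazard_fit")
}

test_that("cumulative risk summaries match the per-month product", {
  # constant hazard h: summary = 1 - (1 - h)^36
  h <- 0.01
  arr <- make_array(subject_id = rep(1:3, each = 2), month = rep(0:1, 3),
                    score_A = rep(0, 6), score_S = rep(0, 6),
                    event = rep(0L, 6))
  fit <- fake_fit(qlogis(h))
  rs <- person_risk_summary(fit, arr)
  expect_equal(unname(rs), rep(1 - (1 - h)^36, 3), tolerance = 1e-12)

  # 3-person fixture with differing hazards: brute-force product oracle,
  # months beyond observation carry the last observed monthly score
  fit2 <- fake_fit(-3, beta_A = 0.6, beta_S = 0.4)
  arr2 <- make_array(subject_id = c(1, 1, 2, 2, 2, 3),
                     month = c(0, 1, 0, 1, 2, 0),
                     score_A = c(0.2, 0.5, -1, -0.5, -0.2, 2),
                     score_S = c(1, 1, -0.5, -0.5, -0.5, 0.3),
                     event = c(0L, 0L, 0L, 0L, 0L, 1L))
  rs2 <- person_risk_summary(fit2, arr2)
  oracle <- function(a_obs, s) {
    a <- c(a_obs, rep(a_obs[length(a_obs)], 36 - length(a_obs)))
    1 - prod(1 - plogis(-3 + 0.6 * a + 0.4 * s))
  }
  expect_equal(unname(rs2),
               c(oracle(c(0.2, 0.5), 1), oracle(c(-1, -0.5, -0.2), -0.5),
                 oracle(2, 0.3)),
               tolerance = 1e-12)
  # uniformly higher hazard ranks higher
  expect_gt(rs2["3"], rs2["1"])
  expect_gt(rs2["1"], rs2["2"])
})

test_that("the mean-log-odds alternative averages observed months only", {
  fit <- fake_fit(-2, beta_A = 1, beta_S = 0)
  arr <- make_array(subject_id = c(1, 1, 2), month = c(0, 1, 0),
                    score_A = c(0, 1, -1), score_S = rep(0, 3),
                    event = rep(0L, 3))
  rs <- person_risk_summary(fit, arr, method = "mean_log_odds")
  expect_equal(unname(rs), c(-2 + 0.5, -3), tolerance = 1e-12)
})

test_that("ventile assignment respects weights, ties and stability", {
  # 20 equal-weight persons with distinct scores: one per ventile
  s <- setNames(rnorm(20), 1:20)
  v <- assign_ventiles(s)
  expect_identical(sort(unname(v)), 1:20)
  expect_identical(unname(v[order(s)]), 1:20)
  # all scores equal: stable order, warning
  expect_warning(v0 <- assign_ventiles(setNames(rep(1, 40), 1:40)),
                 "stable order")
  expect_identical(unname(v0), rep(1:20, each = 2))
  # weighted boundaries match a cumulative-weight scan oracle
  set.seed(101)
  n <- 157
  sc <- rnorm(n); w <- runif(n, 0.2, 4)
  v_w <- assign_ventiles(setNames(sc, 1:n), w)
  o <- order(sc)
  cw <- cumsum(w[o]) / sum(w)
  v_oracle <- integer(n)
  v_oracle[o] <- as.integer(pmin(pmax(ceiling(cw * 20 - 1e-9), 1), 20))
  expect_identical(unname(v_w), v_oracle)
  expect_error(assign_ventiles(rnorm(10)), "fewer persons")
})

test_that("concentration of risk tallies weighted events per ventile", {
  # 10 equal-weight events, 4 in the top ventile
  n <- 200
  ev <- rep(NA_integer_, n)
  ev[c(1:6, 197:200)] <- 5L
  subj <- make_subjects(ev, rep(30L, n))
  subj$last_observed_month[!is.na(ev)] <- 5L
  labels <- setNames(rep(1:20, each = 10), subj$subject_id)
  conc <- concentration_of_risk(labels, subj)
  expect_equal(conc$pct_cases[20], 40)
  expect_equal(sum(conc$pct_cases), 100, tolerance = 1e-9)
  expect_equal(unname(attr(conc, "top")["top1"]), 40)
  # weighted tally oracle on a random fixture
  set.seed(103)
  w <- runif(n, 0.3, 3)
  subj_w <- subj; subj_w$weight <- w
  conc_w <- concentration_of_risk(labels, subj_w)
  for (k in c(1, 7, 20)) {
    expect_equal(conc_w$pct_cases[k],
                 100 * sum(w[!is.na(ev) & labels == k]) /
                   sum(w[!is.na(ev)]), tolerance = 1e-12)
  }
  expect_error(concentration_of_risk(labels,
                                     make_subjects(NA_integer_, 3L)[0, ]),
               "no observed events")
})

test_that("observed PPV is weighted events per 1000 person-months", {
  # 2 events in 500 person-months -> 4.0
  arr <- make_array(subject_id = rep(1:50, each = 10),
                    month = rep(0:9, 50),
                    score_A = 0, score_S = 0,
                    event = c(rep(0L, 498), 1L, 1L))
  labels <- setNames(rep(1:20, length.out = 50), 1:50)
  # put the two event subjects (49, 50) in known ventiles
  labels[c("49", "50")] <- c(20L, 20L)
  ppv <- observed_ppv(labels, arr)
  expect_equal(ppv$events_per_1000pm[20],
               1000 * 2 / sum(labels[arr$subject_id |> as.character()] == 20))
  # totals identity: rate x person-months recovers total events
  tot <- sum(vapply(1:20, function(k) {
    pm <- sum(arr$weight[labels[as.character(arr$subject_id)] == k])
    ppv$events_per_1000pm[k] * pm / 1000
  }, numeric(1)))
  expect_equal(tot, 2, tolerance = 1e-10)
})

test_that("proportional improvement reproduces published ratio examples", {
  expect_identical(proportional_improvement(42.0, 32.4), 29.6)
  expect_identical(proportional_improvement(3.4, 2.9), 17.2)
  expect_identical(proportional_improvement(5, 5), 0)
  expect_error(proportional_improvement(5, 0), "positive")
})

test_that("stronger survey effects concentrate more risk on top", {
  top1 <- vapply(c(0, 0.6, 1.2), function(bS) {
    mean(vapply(1:3, function(s) {
      cfg <- test_cfg(seed = 7000 + s, n_subjects = 1200, beta_S = bS,
                      alpha_base = -5)
      subj <- simulate_study(cfg)
      arr <- standardize_scores(expand_person_months(subj))
      fit <- fit_hazard_model(arr, model_spec("M6"), design_cov = FALSE)
      rep <- ventile_report(fit, subj, arr)
      attr(rep, "top")["concentration_pct", "top1"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(top1[2] > top1[1] && top1[3] > top1[2])
})

test_that("adding the survey score rarely hurts top-ventile concentration", {
  # a survey effect strong enough that the directional gain exceeds the
  # binomial noise of the ~5% tail
  wins <- vapply(1:12, function(s) {
    cfg <- test_cfg(seed = 8100 + s, n_subjects = 2500, beta_A = 0.4,
                    beta_S = 0.9, alpha_base = -5)
    subj <- simulate_study(cfg)
    arr <- standardize_scores(expand_person_months(subj))
    f2 <- fit_hazard_model(arr, model_spec("M2"), design_cov = FALSE)
    f6 <- fit_hazard_model(arr, model_spec("M6"), design_cov = FALSE)
    r2 <- ventile_report(f2, subj, arr)
    r6 <- ventile_report(f6, subj, arr)
    attr(r6, "top")["concentration_pct", "top1"] >=
      attr(r2, "top")["concentration_pct", "top1"]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
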