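test_that("design matrices have the documented columns and nesting", {
  arr <- make_array(subject_id = rep(1:4, each = 3),
                    month = rep(0:2, 4),
                    score_A = rnorm(12), score_S = rep(rnorm(4), each = 3),
                    event = rep(c(0L, 0L, 1L), 4))
  X1 <- build_design_matrix(arr, model_spec("M1"))
  expect_identical(colnames(X1), c("(Intercept)", "T1", "T2"))
  X2 <- build_design_matrix(arr, model_spec("M2"))
  expect_identical(setdiff(colnames(X2), colnames(X1)), "A")
  X6 <- build_design_matrix(arr, model_spec("M6"))
  X7 <- build_design_matrix(arr, model_spec("M7"))
  expect_identical(setdiff(colnames(X7), colnames(X6)),
                   c("S:T13_24", "S:T25p"))
  expect_error(model_spec(terms = c("T", "TS")), "main effect")
  expect_error(model_spec(terms = c("A", "S")), "T required")
})

test_that("an intercept-only fit recovers the closed-form event rate", {
  n <- 100
  arr <- make_array(subject_id = 1:n, month = rep(0L, n),
                    score_A = rnorm(n), score_S = rnorm(n),
                    event = c(rep(1L, 5), rep(0L, n - 5)),
                    cluster_id = rep(1:5, each = 20))
  fit <- fit_hazard_model(arr, model_spec("M1"))
  expect_equal(unname(coef(fit)["(Intercept)"]), qlogis(0.05),
               tolerance = 1e-6)
})

test_that("duplicating rows and halving weights leaves the fit unchanged", {
  arr <- oracle_fixture(seed = 31)
  fit <- fit_hazard_model(arr, model_spec("M6"), design_cov = FALSE)
  arr2 <- rbind(arr, arr)
  arr2$weight <- arr2$weight / 2
  class(arr2) <- class(arr)
  fit2 <- fit_hazard_model(arr2, model_spec("M6"), design_cov = FALSE)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("coefficients match an independent general-purpose optimizer", {
  arr <- oracle_fixture(seed = 37, n_subjects = 80)
  expect_gte(nrow(arr), 450)
  fit <- fit_hazard_model(arr, model_spec("M6"), design_cov = FALSE)
  X <- as.matrix(fit$X); y <- fit$y; w <- fit$w
  nll <- function(b) {
    mu <- plogis(drop(X %*% b))
    -sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
  gr <- function(b) -drop(crossprod(X, w * (y - plogis(drop(X %*% b)))))
  o <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-15))
  expect_lt(max(abs(o$par - unname(coef(fit)))), 1e-6)
  expect_equal(-o$value, fit$loglik, tolerance = 1e-9)
})

test_that("log-likelihood is non-decreasing along the nested ladder", {
  arr <- sim_array(test_cfg(seed = 41, n_subjects = 1500,
                            alpha_base = -4.3))
  lls <- vapply(c("M1", "M2", "M3", "M4", "M5"), function(l) {
    fit_hazard_model(arr, model_spec(l), design_cov = FALSE)$loglik
  }, numeric(1))
  expect_true(all(diff(lls[c("M1", "M2", "M3", "M5")]) > -1e-8))
  expect_true(all(diff(lls[c("M1", "M2", "M4", "M5")]) > -1e-8))
})

test_that("cluster sandwich matches a brute-force double loop", {
  arr <- oracle_fixture(seed = 43, n_subjects = 60, n_clusters = 10)
  fit <- fit_hazard_model(arr, model_spec("M6"))
  V <- fit$vcov_design
  # naive accumulation oracle
  X <- as.matrix(fit$X)
  resid <- fit$w * (fit$y - fit$mu)
  cl <- unique(fit$cluster)
  meat <- matrix(0, ncol(X), ncol(X))
  for (c_id in cl) {
    g <- colSums(X[fit$cluster == c_id, , drop = FALSE] *
                   resid[fit$cluster == c_id])
    meat <- meat + tcrossprod(g)
  }
  meat <- meat * length(cl) / (length(cl) - 1)
  A <- crossprod(sqrt(fit$w * fit$mu * (1 - fit$mu)) * X)
  V_naive <- solve(A, meat) %*% solve(A)
  expect_lt(max(abs(V - V_naive)), 1e-10)
})

test_that("degenerate clustering reduces to the row-level robust sandwich", {
  arr <- oracle_fixture(seed = 47, n_subjects = 50)
  arr$weight <- 1
  arr$cluster_id <- seq_len(nrow(arr))   # every row its own cluster
  fit <- fit_hazard_model(arr, model_spec("M2"), design_cov = FALSE)
  V <- sandwich_covariance(fit, cadjust = FALSE)
  X <- as.matrix(fit$X)
  resid <- fit$y - fit$mu
  meat <- crossprod(X * resid)
  A <- crossprod(sqrt(fit$mu * (1 - fit$mu)) * X)
  V_hc0 <- solve(A, meat) %*% solve(A)
  expect_lt(max(abs(V - V_hc0)), 1e-10)
})

test_that("the sandwich is invariant to rescaling all weights", {
  arr <- oracle_fixture(seed = 53)
  fit <- fit_hazard_model(arr, model_spec("M6"))
  arr2 <- arr; arr2$weight <- arr$weight * 7
  fit2 <- fit_hazard_model(arr2, model_spec("M6"))
  expect_equal(fit2$vcov_design, fit$vcov_design, tolerance = 1e-10)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-10)
})

test_that("a single sampling cluster is rejected", {
  arr <- oracle_fixture(seed = 59, n_subjects = 30)
  arr$cluster_id <- 1L
  expect_error(fit_hazard_model(arr, model_spec("M2")), "single")
})

test_that("Wald tests reproduce closed forms and a linear-algebra oracle", {
  fake <- structure(list(coefficients = c(b = 2),
                         vcov_design = matrix(1, dimnames = list("b", "b")),
                         vcov_model = matrix(1, dimnames = list("b", "b")),
                         term_cols = list(), converged = TRUE),
                    class = "hazard_fit")
  wt <- wald_test(fake, "b")
  expect_equal(wt$statistic, 4)
  expect_identical(wt$df, 1L)
  expect_equal(wt$p_value, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  fake$coefficients <- c(b = 0)
  wt0 <- wald_test(fake, "b")
  expect_equal(wt0$statistic, 0)
  expect_equal(wt0$p_value, 1)

  set.seed(61)
  b3 <- rnorm(3)
  R <- matrix(rnorm(9), 3)
  V3 <- crossprod(R) + diag(3)
  nm <- c("x1", "x2", "x3")
  fake3 <- structure(list(coefficients = setNames(b3, nm),
                          vcov_design = `dimnames<-`(V3, list(nm, nm)),
                          term_cols = list(), converged = TRUE),
                     class = "hazard_fit")
  wt3 <- wald_test(fake3, nm)
  expect_equal(wt3$statistic, drop(t(b3) %*% solve(V3) %*% b3),
               tolerance = 1e-10)
  expect_identical(wt3$df, 3L)
})

test_that("nested comparisons test the added block with the right df", {
  arr <- sim_array(test_cfg(seed = 67, n_subjects = 1500,
                            alpha_base = -4.3))
  f1 <- fit_hazard_model(arr, model_spec("M1"))
  f2 <- fit_hazard_model(arr, model_spec("M2"))
  f6 <- fit_hazard_model(arr, model_spec("M6"))
  f7 <- fit_hazard_model(arr, model_spec("M7"))
  expect_identical(compare_nested(f1, f2)$df, 1L)
  expect_identical(compare_nested(f6, f7)$df, 2L)
  expect_error(compare_nested(f2, f2), "identical")
  f3 <- fit_hazard_model(arr, model_spec("M3"))
  f4 <- fit_hazard_model(arr, model_spec("M4"))
  expect_error(compare_nested(f3, f4), "not nested")
})

test_that("predictions satisfy the maximum-likelihood balance identity", {
  arr <- oracle_fixture(seed = 71)
  fit <- fit_hazard_model(arr, model_spec("M6"), design_cov = FALSE)
  keep <- !(arr$month %in% fit$dropped_months)
  eta <- predict_log_odds(fit, arr[keep, ])
  w <- arr$weight[keep]
  expect_equal(sum(w * plogis(eta)) / sum(w),
               sum(w * arr$event[keep]) / sum(w), tolerance = 1e-8)
})

test_that("predictions equal a manual dot product on a small fixture", {
  arr <- make_array(subject_id = rep(1L, 5), month = 0:4,
                    score_A = c(0.5, -1, 2, 0, 1),
                    score_S = rep(0.7, 5), event = c(0L, 0L, 0L, 0L, 1L))
  spec <- model_spec(terms = c("T", "A", "S"))
  beta <- c("(Intercept)" = -2, T1 = 0.1, T2 = 0.2, T3 = 0.3, T4 = 0.4,
            A = 0.5, S = -0.25)
  fake <- structure(list(coefficients = beta, spec = spec,
                         dummy_months = 1:4, ref_month = 0L,
                         term_cols = list(T = paste0("T", 1:4), A = "A",
                                          S = "S")),
                    class = "hazard_fit")
  eta <- predict_log_odds(fake, arr)
  manual <- -2 + c(0, 0.1, 0.2, 0.3, 0.4) + 0.5 * arr$score_A -
    0.25 * arr$score_S
  expect_equal(unname(eta), manual, tolerance = 1e-12)
  # months outside the basis fall back to reference coding
  arr5 <- arr; arr5$month <- arr5$month + 10L
  eta5 <- predict_log_odds(fake, arr5)
  expect_identical(attr(eta5, "fallback_months"), c(10L, 11L, 12L, 13L, 14L))
})

test_that("separation is flagged rather than silently returned", {
  set.seed(73)
  n <- 200
  S <- rnorm(n)
  arr <- make_array(subject_id = 1:n, month = rep(0L, n),
                    score_A = rnorm(n), score_S = S,
                    event = as.integer(S > 1),
                    cluster_id = rep(1:10, each = 20))
  fit <- suppressWarnings(
    fit_hazard_model(arr, model_spec(terms = c("T", "S")),
                     design_cov = FALSE))
  expect_true(fit$separation_suspected || !fit$converged)
})

test_that("design-based and model-based SEs agree without clustering", {
  cfg <- test_cfg(seed = 79, weight_sd = 0)
  subj <- simulate_study(cfg)
  subj$cluster_id <- subj$subject_id      # one subject per cluster
  arr <- standardize_scores(expand_person_months(subj))
  fit <- fit_hazard_model(arr, model_spec("M6"))
  for (tm in c("A", "S")) {
    se_d <- sqrt(fit$vcov_design[tm, tm])
    se_m <- sqrt(fit$vcov_model[tm, tm])
    expect_lt(abs(se_d / se_m - 1), 0.2)
  }
})

test_that("models without events are rejected", {
  arr <- make_array(subject_id = 1:10, month = rep(0L, 10),
                    score_A = rnorm(10), score_S = rnorm(10),
                    event = rep(0L, 10))
  expect_error(fit_hazard_model(arr, model_spec("M1")), "no events")
})
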