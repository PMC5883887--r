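#' Fit a survey-weighted discrete-time logistic hazard model
#'
#' Maximizes the weight-multiplied Bernoulli log-likelihood
#' `sum_i w_i [y_i log mu_i + (1 - y_i) log(1 - mu_i)]` over person-month
#' rows by iteratively reweighted least squares on a sparse design
#' matrix.  Convergence requires a relative log-likelihood change below
#' `ll_tol` or a gradient infinity-norm below `grad_tol` (with
#' step-halving if a step would decrease the likelihood).
#'
#' Months containing no (weighted) events — or, symmetrically, only
#' events — are dropped together with their rows and dummies before
#' fitting: with a per-month dummy basis the remaining coefficients'
#' maximum-likelihood estimates are unchanged (the dropped months'
#' hazard tends to 0 or 1 and their rows contribute nothing to the
#' profiled log-likelihood at the limit), while the perfect separation
#' such months would otherwise cause is avoided.  The dropped months are
#' recorded in the result and reference-coded during prediction.
#'
#' @param array a standardized person-month array.
#' @param spec a [model_spec()].
#' @param design optional [survey_design()] overriding embedded
#'   weight/cluster columns.
#' @param design_cov compute the design-based (cluster sandwich)
#'   covariance via [sandwich_covariance()] and store it in the fit.
#' @param drop_empty_months drop months without events (see Details).
#' @param ll_tol,grad_tol,max_iter convergence controls.
#' @return an object of class `hazard_fit` with elements `coefficients`,
#'   `loglik`, `vcov_model`, `vcov_design`, `n` (person-month rows
#'   used), `n_events`, `iterations`, `converged`, `gradient_norm`,
#'   `dropped_months`, `dummy_months`, `ref_month`, `spec`, `term_cols`,
#'   plus the fitting data needed by [sandwich_covariance()] and
#'   [predict_log_odds()].
#' @export
fit_hazard_model <- function(array, spec, design = NULL,
                             design_cov = TRUE, drop_empty_months = TRUE,
                             ll_tol = 1e-10, grad_tol = 1e-8,
                             max_iter = 100L) {
  stopifnot(inherits(spec, "model_spec"))
  array <- apply_design(array, design)
  dropped_months <- integer(0)
  if (drop_empty_months) {
    # a month whose rows are all non-events (or all events) drives its own
    # dummy to -Inf (+Inf); dropping the month leaves the remaining MLEs
    # unchanged and avoids the separation
    wev <- tapply(array$weight * array$event, array$month, sum)
    wnon <- tapply(array$weight * (1 - array$event), array$month, sum)
    dropped_months <- as.integer(names(wev))[wev == 0 | wnon == 0]
    if (length(dropped_months)) {
      array <- array[!(array$month %in% dropped_months), , drop = FALSE]
    }
  }
  if (nrow(array) == 0L || sum(array$event) == 0L) {
    stop("no events in the person-month array; model cannot be fit",
         call. = FALSE)
  }
  X <- build_design_matrix(array, spec)
  y <- array$event
  w <- array$weight
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(sum(w * y) / sum(w), 1e-8), 1 - 1e-8))
  loglik_at <- function(eta) {
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-15), 1 - 1e-15)
    sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
  eta <- as.vector(X %*% beta)
  ll <- loglik_at(eta)
  converged <- FALSE
  gnorm <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    g <- as.vector(Matrix::crossprod(X, w * (y - mu)))
    gnorm <- max(abs(g))
    if (gnorm < grad_tol) { converged <- TRUE; break }
    wirls <- w * mu * (1 - mu)
    H <- as.matrix(Matrix::crossprod(sqrt(wirls) * X))
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) {
      if (iter == 1L) {
        stop("design matrix is rank deficient on the observed data",
             call. = FALSE)
      }
      break   # information collapsed mid-path (separation); keep last beta
    }
    delta <- backsolve(ch, forwardsolve(t(ch), g))
    # trust region: huge Newton steps in low-curvature coordinates (sparse
    # month dummies) overshoot; cap and let the next iteration re-solve
    mx <- max(abs(delta))
    if (mx > 5) delta <- delta * (5 / mx)
    step <- 1
    improved <- FALSE
    repeat {
      beta_new <- beta + step * delta
      eta_new <- as.vector(X %*% beta_new)
      ll_new <- loglik_at(eta_new)
      if (ll_new >= ll - 1e-12) { improved <- TRUE; break }
      if (step < 1e-8) break
      step <- step / 2
    }
    if (!improved) break   # no ascent possible along the damped step
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    beta <- beta_new; eta <- eta_new; ll <- ll_new
    if (rel < ll_tol) {
      mu <- stats::plogis(eta)
      gnorm <- max(abs(as.vector(Matrix::crossprod(X, w * (y - mu)))))
      converged <- TRUE
      break
    }
  }
  mu <- stats::plogis(eta)
  wirls <- w * mu * (1 - mu)
  H <- as.matrix(Matrix::crossprod(sqrt(wirls) * X))
  vcov_model <- tryCatch(chol2inv(chol(H)), error = function(e) {
    warning("information matrix numerically singular; ",
            "model-based covariance via pseudo-inverse")
    MASS_ginv(H)
  })
  dimnames(vcov_model) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  fit <- structure(list(
    coefficients = beta,
    loglik = ll,
    vcov_model = vcov_model,
    vcov_design = NULL,
    n = nrow(array),
    n_events = sum(y),
    weighted_events = sum(w * y),
    iterations = iter,
    converged = converged,
    gradient_norm = gnorm,
    separation_suspected = any(abs(beta) > 20),
    dropped_months = dropped_months,
    dummy_months = attr(X, "dummy_months"),
    ref_month = min(array$month),
    spec = spec,
    term_cols = attr(X, "term_cols"),
    X = X, y = y, w = w, mu = mu,
    cluster = array$cluster_id,
    subject_id = array$subject_id),
    class = "hazard_fit")
  if (!converged) {
    warning("IRLS did not converge in ", max_iter,
            " iterations (gradient norm ", format(gnorm), ")")
  }
  if (design_cov) fit$vcov_design <- sandwich_covariance(fit)
  fit
}

# minimal Moore-Penrose fallback (avoids importing MASS for one corner)
MASS_ginv <- function(H, tol = 1e-12) {
  e <- eigen(H, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' @export
coef.hazard_fit <- function(object, ...) object$coefficients

#' @export
logLik.hazard_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
vcov.hazard_fit <- function(object, type = c("design", "model"), ...) {
  type <- match.arg(type)
  if (type == "design") {
    if (is.null(object$vcov_design)) {
      stop("design-based covariance not computed; see sandwich_covariance()",
           call. = FALSE)
    }
    object$vcov_design
  } else object$vcov_model
}

#' Coefficient table of a hazard fit
#'
#' @param fit a `hazard_fit`.
#' @param conf_level confidence level for the odds-ratio interval
#'   (design-based standard errors).
#' @param all_terms include month dummies (default keeps only score
#'   terms, the analysis surface).
#' @return `data.frame` with term, estimate, model-based and design-based
#'   SE, odds ratio and CI bounds.
#' @export
coef_table <- function(fit, conf_level = 0.95, all_terms = FALSE) {
  stopifnot(inherits(fit, "hazard_fit"))
  b <- fit$coefficients
  keep <- if (all_terms) names(b) else
    setdiff(names(b), c("(Intercept)", fit$term_cols$T))
  se_m <- sqrt(diag(fit$vcov_model))[keep]
  se_d <- if (!is.null(fit$vcov_design)) {
    sqrt(diag(fit$vcov_design))[keep]
  } else rep(NA_real_, length(keep))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = keep,
             estimate = unname(b[keep]),
             se_model = unname(se_m),
             se_design = unname(se_d),
             or = exp(unname(b[keep])),
             ci_low = exp(unname(b[keep] - z * se_d)),
             ci_high = exp(unname(b[keep] + z * se_d)),
             stringsAsFactors = FALSE)
}

#' @export
#' @method print hazard_fit
print.hazard_fit <- function(x, ...) {
  cat(sprintf(
    "Discrete-time hazard model %s (%s)\n",
    x$spec$label, paste(x$spec$terms, collapse = " + ")))
  cat(sprintf(
    "  %d person-months, %d events, logLik %.4f, %d IRLS iterations%s\n",
    x$n, x$n_events, x$loglik, x$iterations,
    if (x$converged) "" else " [NOT CONVERGED]"))
  if (length(x$dropped_months)) {
    cat("  months dropped (no events): ",
        paste(x$dropped_months, collapse = ", "), "\n", sep = "")
  }
  tab <- coef_table(x)
  if (nrow(tab)) {
    cat("  score terms (odds ratios, design-based 95% CI):\n")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("    %-10s OR %.2f (%.2f-%.2f)\n", tab$term[i],
                  tab$or[i], tab$ci_low[i], tab$ci_high[i]))
    }
  }
  invisible(x)
}

#' Predicted log-odds per person-month row
#'
#' Linear predictor of a fitted hazard model evaluated on a person-month
#' array.  Months absent from the fit's dummy basis (dropped as
#' event-free during fitting, or never observed) are coded as the
#' reference month; when this happens the result carries a
#' `fallback_months` attribute naming them.
#'
#' @param fit a `hazard_fit`.
#' @param array a person-month array with the columns the specification
#'   needs.
#' @return numeric vector of predicted log-odds, one per row.
#' @export
predict_log_odds <- function(fit, array) {
  stopifnot(inherits(fit, "hazard_fit"))
  X <- build_design_matrix(array, fit$spec, dummy_months = fit$dummy_months,
                           unseen = "reference")
  eta <- as.vector(X %*% fit$coefficients)
  outside <- setdiff(sort(unique(array$month)),
                     c(fit$ref_month, fit$dummy_months))
  if (length(outside)) attr(eta, "fallback_months") <- outside
  eta
}
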