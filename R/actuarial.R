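#' Weighted quantiles (inverse-CDF convention)
#'
#' Smallest value whose cumulative weight reaches the requested
#' probability; ties break toward the lower value.  Equal weights
#' reproduce `quantile(type = 1)`.
#'
#' @param x numeric values.
#' @param w positive weights (default equal).
#' @param probs probabilities.
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs) {
  stopifnot(length(x) == length(w), all(w > 0), length(x) > 0)
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Actuarial life table
#'
#' Weighted life-table (actuarial) estimator over monthly intervals
#' `j = 0, 1, ...`: with `n_j` the weight at risk entering month `j`,
#' `d_j` the weighted events and `c_j` the weighted withdrawals in the
#' month, the effective denominator is `n_j - c_j / 2` (withdrawals
#' assumed at risk for half the interval), the conditional hazard is
#' `q_j = d_j / (n_j - c_j / 2)`, and survival is the running product of
#' `1 - q_j`.
#'
#' @param subjects a subject table (columns `event_month`,
#'   `last_observed_month`, `weight`).
#' @param design optional [survey_design()].
#' @param horizon number of months covered (default 36; projection
#'   beyond 36 months is not supported because follow-up there is too
#'   sparse).
#' @return a `data.frame` of class `life_table` with one row per month:
#'   `month`, `n_at_risk`, `d_events`, `c_censored`, `effective_n`,
#'   `hazard`, `survival`, `morbid_risk` (cumulative, per 1).
#' @export
life_table <- function(subjects, design = NULL, horizon = 36L) {
  if (nrow(subjects) == 0L) stop("empty cohort", call. = FALSE)
  if (horizon > 36L) {
    stop("horizon beyond 36 months is not supported (follow-up too sparse)",
         call. = FALSE)
  }
  subjects <- apply_design(subjects, design)
  w <- subjects$weight
  ev <- subjects$event_month
  last <- subjects$last_observed_month
  months <- 0:(horizon - 1L)
  is_event <- !is.na(ev)
  d <- vapply(months, function(j) sum(w[is_event & ev == j]), numeric(1))
  cns <- vapply(months, function(j) sum(w[!is_event & last == j]),
                numeric(1))
  n <- numeric(horizon)
  n[1] <- sum(w)
  if (horizon > 1L) {
    for (j in 2:horizon) n[j] <- n[j - 1] - d[j - 1] - cns[j - 1]
  }
  eff <- n - cns / 2
  q <- ifelse(eff > 0, d / eff, 0)
  q <- pmin(pmax(q, 0), 1)
  surv <- cumprod(1 - q)
  out <- data.frame(month = months, n_at_risk = n, d_events = d,
                    c_censored = cns, effective_n = eff, hazard = q,
                    survival = surv, morbid_risk = 1 - surv)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Cumulative morbid risk per 1000
#'
#' `1000 * (1 - S_horizon)` from an actuarial life table: the projected
#' cumulative probability of a first occurrence within the horizon, per
#' 1000 soldiers.
#'
#' @param lt a [life_table()].
#' @param horizon months (must be covered by the table).
#' @return risk per 1000 (scalar).
#' @export
morbid_risk <- function(lt, horizon = 36L) {
  stopifnot(inherits(lt, "life_table"))
  if (horizon < 1L || horizon > nrow(lt)) {
    stop("horizon of ", horizon, " months is beyond the life table",
         call. = FALSE)
  }
  1000 * (1 - prod(1 - lt$hazard[seq_len(horizon)]))
}

#' Median and interquartile range of months to first occurrence
#'
#' Weighted quantiles of the event month among subjects with an observed
#' first occurrence (inverse-CDF convention, ties toward the lower
#' month).
#'
#' @param subjects a subject table.
#' @param design optional [survey_design()].
#' @return named numeric vector `(median, q25, q75)`.
#' @export
median_iqr_event_time <- function(subjects, design = NULL) {
  subjects <- apply_design(subjects, design)
  has <- !is.na(subjects$event_month)
  if (!any(has)) stop("no observed events", call. = FALSE)
  q <- weighted_quantile(subjects$event_month[has], subjects$weight[has],
                         c(0.5, 0.25, 0.75))
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Actuarially projected positive predictive value of a subgroup
#'
#' Cumulative cases per 1000 soldiers at the horizon in a subgroup
#' (typically a predicted-risk ventile), estimated with the actuarial
#' life table restricted to the subgroup so that varying follow-up is
#' adjusted for.
#'
#' @param subgroup a subject table restricted to the subgroup.
#' @param design optional [survey_design()].
#' @param horizon months (default 36).
#' @return projected cases per 1000 soldiers (scalar).
#' @export
projected_ppv <- function(subgroup, design = NULL, horizon = 36L) {
  morbid_risk(life_table(subgroup, design, horizon), horizon)
}
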