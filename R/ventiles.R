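#' Reduce monthly predictions to one risk rank per person
#'
#' The default summary is the predicted 36-month cumulative risk
#' `1 - prod_m (1 - expit(eta_im))`, evaluating the fitted model over
#' months `0 .. horizon-1`: observed months use the observed monthly
#' score, months beyond a person's observation are extrapolated with the
#' fitted time effects and the person's last observed monthly score.
#' The alternative `"mean_log_odds"` summary averages the predicted
#' log-odds over the person's observed months only.
#'
#' @param fit a `hazard_fit`.
#' @param array the person-month array the fit was built from.
#' @param horizon months of the cumulative-risk product (default 36).
#' @param method `"cumulative"` (default) or `"mean_log_odds"`.
#' @return named numeric vector of per-person summaries (names =
#'   subject ids, in first-appearance order).
#' @export
person_risk_summary <- function(fit, array, horizon = 36L,
                                method = c("cumulative", "mean_log_odds")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "hazard_fit"))
  if (nrow(array) == 0L) stop("empty person-month array", call. = FALSE)
  ids <- unique(array$subject_id)
  if (method == "mean_log_odds") {
    eta <- predict_log_odds(fit, array)
    out <- tapply(eta, factor(array$subject_id, levels = ids), mean)
    return(stats::setNames(as.vector(out), as.character(ids)))
  }
  idx <- match(array$subject_id, ids)
  n <- length(ids)
  # per person: observed A by month, S, last observed A
  Amat <- matrix(NA_real_, n, horizon)
  obs <- array$month < horizon
  Amat[cbind(idx[obs], array$month[obs] + 1L)] <- array$score_A[obs]
  o <- order(idx, array$month)
  last_row <- o[!duplicated(idx[o], fromLast = TRUE)]
  lastA <- numeric(n)
  lastA[idx[last_row]] <- array$score_A[last_row]
  S <- numeric(n)
  first_row <- o[!duplicated(idx[o])]
  S[idx[first_row]] <- array$score_S[first_row]
  for (j in seq_len(horizon)) {
    miss <- is.na(Amat[, j])
    if (any(miss)) Amat[miss, j] <- lastA[miss]
  }
  ext <- data.frame(
    subject_id = rep(ids, each = horizon),
    month = rep.int(0:(horizon - 1L), n),
    score_A = as.vector(t(Amat)),
    score_S = rep(S, each = horizon))
  eta <- predict_log_odds(fit, ext)
  log_surv <- stats::plogis(eta, lower.tail = FALSE, log.p = TRUE)
  risk <- 1 - exp(rowsum(log_surv, group = rep(seq_len(n), each = horizon),
                         reorder = FALSE))
  stats::setNames(as.vector(risk), as.character(ids))
}

#' Assign weighted risk ventiles
#'
#' Ranks persons by a risk summary and cuts the weighted population into
#' `n_groups` strata of equal weight (default 20 ventiles of 5% each).
#' Ventile `n_groups` holds the highest predicted risk.  Boundary ties
#' fall in the lower ventile; exact score ties keep the stable input
#' order.
#'
#' @param summaries named numeric vector of per-person risk summaries
#'   (see [person_risk_summary()]).
#' @param weights per-person weights aligned with `summaries` (default
#'   equal).
#' @param n_groups number of strata (default 20).
#' @return named integer vector of ventile labels (1 = lowest risk).
#' @export
assign_ventiles <- function(summaries, weights = NULL, n_groups = 20L) {
  n <- length(summaries)
  if (n < n_groups) {
    stop("fewer persons (", n, ") than ventiles (", n_groups, ")",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  if (length(unique(summaries)) == 1L) {
    warning("all risk summaries equal; ventiles assigned by stable order")
  }
  o <- order(summaries)              # stable for ties
  cw <- cumsum(weights[o]) / sum(weights)
  v <- pmin.int(pmax.int(ceiling(cw * n_groups - 1e-9), 1L), n_groups)
  out <- integer(n)
  out[o] <- as.integer(v)
  stats::setNames(out, names(summaries))
}

# match per-subject labels onto a table carrying subject_id
labels_for <- function(labels, subject_id) {
  if (!is.null(names(labels))) {
    out <- labels[match(as.character(subject_id), names(labels))]
    if (anyNA(out)) stop("ventile labels do not cover all subjects",
                         call. = FALSE)
    unname(out)
  } else {
    if (length(labels) != length(subject_id)) {
      stop("unnamed labels must align with subjects", call. = FALSE)
    }
    labels
  }
}

#' Concentration of risk by ventile
#'
#' Weighted percentage of all observed cases that fall in each
#' predicted-risk ventile; under a useless model each ventile holds the
#' 5% expected by chance.
#'
#' @param labels ventile labels (named by subject id, or aligned with
#'   `subjects`).
#' @param subjects a subject table.
#' @param design optional [survey_design()].
#' @param n_groups number of strata used in `labels`.
#' @return `data.frame` (ventile, pct_cases) with attribute `top`: the
#'   cumulative percentages in the top 1, 2 and 3 ventiles.
#' @export
concentration_of_risk <- function(labels, subjects, design = NULL,
                                  n_groups = 20L) {
  subjects <- apply_design(subjects, design)
  v <- labels_for(labels, subjects$subject_id)
  has <- !is.na(subjects$event_month)
  if (!any(has)) stop("no observed events", call. = FALSE)
  wev <- subjects$weight * has
  tot <- sum(wev)
  pct <- vapply(seq_len(n_groups), function(k) sum(wev[v == k]) / tot * 100,
                numeric(1))
  out <- data.frame(ventile = seq_len(n_groups), pct_cases = pct)
  attr(out, "top") <- c(top1 = pct[n_groups],
                        top2 = sum(pct[n_groups - (0:1)]),
                        top3 = sum(pct[n_groups - (0:2)]))
  out
}

#' Observed positive predictive value by ventile
#'
#' Weighted events per 1000 weighted person-months at risk within each
#' ventile.
#'
#' @param labels ventile labels (named by subject id, or aligned with
#'   the array's subjects).
#' @param array a person-month array.
#' @param design optional [survey_design()].
#' @param n_groups number of strata used in `labels`.
#' @return `data.frame` (ventile, events_per_1000pm) with attribute
#'   `top`: the pooled rates in the top 1, 2 and 3 ventiles.
#' @export
observed_ppv <- function(labels, array, design = NULL, n_groups = 20L) {
  array <- apply_design(array, design)
  v <- labels_for(labels, array$subject_id)
  rate_in <- function(keep) {
    pm <- sum(array$weight[keep])
    if (pm == 0) stop("empty ventile: no person-months at risk",
                      call. = FALSE)
    sum(array$weight[keep] * array$event[keep]) / pm * 1000
  }
  rates <- vapply(seq_len(n_groups), function(k) rate_in(v == k),
                  numeric(1))
  out <- data.frame(ventile = seq_len(n_groups), events_per_1000pm = rates)
  attr(out, "top") <- c(top1 = rate_in(v == n_groups),
                        top2 = rate_in(v >= n_groups - 1L),
                        top3 = rate_in(v >= n_groups - 2L))
  out
}

#' Proportional improvement between two model metrics
#'
#' `(best / base - 1) * 100`, reported to one decimal: the proportional
#' gain in concentration of risk or positive predictive value of the
#' best-fitting model relative to the administrative-only model.
#'
#' @param best metric under the richer model.
#' @param base metric under the reference model (must be positive).
#' @return percentage improvement, rounded to one decimal (vectorized).
#' @export
proportional_improvement <- function(best, base) {
  if (any(base <= 0)) stop("base metric must be positive", call. = FALSE)
  round((best / base - 1) * 100, 1)
}

#' Per-ventile performance report for one model
#'
#' Assembles the full evaluation of a fitted model: per-ventile weighted
#' respondent share, concentration of risk, observed PPV (events per
#' 1000 person-months) and projected PPV (cases per 1000 soldiers at the
#' horizon), plus the cumulative top-1/2/3 aggregates of each metric.
#'
#' @param fit a `hazard_fit`.
#' @param subjects the subject table.
#' @param array the person-month array the fit used.
#' @param design optional [survey_design()].
#' @param horizon projection horizon in months.
#' @param method ranking method passed to [person_risk_summary()].
#' @param label model label recorded in the report.
#' @return a `data.frame` of class `ventile_report` with attributes
#'   `top` (3 x 4 matrix of top-k aggregates), `model` and `labels`
#'   (the per-person ventile assignment).
#' @export
ventile_report <- function(fit, subjects, array, design = NULL,
                           horizon = 36L,
                           method = c("cumulative", "mean_log_odds"),
                           label = fit$spec$label) {
  subjects <- apply_design(subjects, design)
  rs <- person_risk_summary(fit, array, horizon = horizon,
                            method = match.arg(method))
  w <- subjects$weight[match(names(rs), as.character(subjects$subject_id))]
  v <- assign_ventiles(rs, w)
  conc <- concentration_of_risk(v, subjects)
  oppv <- observed_ppv(v, array)
  vsub <- labels_for(v, subjects$subject_id)
  share <- vapply(1:20, function(k) sum(subjects$weight[vsub == k]) /
                    sum(subjects$weight) * 100, numeric(1))
  proj <- vapply(1:20, function(k) {
    projected_ppv(subjects[vsub == k, , drop = FALSE], horizon = horizon)
  }, numeric(1))
  proj_top <- vapply(1:3, function(k) {
    projected_ppv(subjects[vsub >= 21L - k, , drop = FALSE],
                  horizon = horizon)
  }, numeric(1))
  out <- data.frame(ventile = 1:20,
                    pct_respondents = share,
                    concentration_pct = conc$pct_cases,
                    observed_ppv_per_1000pm = oppv$events_per_1000pm,
                    projected_ppv_per_1000 = proj)
  top <- rbind(concentration_pct = attr(conc, "top"),
               observed_ppv_per_1000pm = attr(oppv, "top"),
               projected_ppv_per_1000 = stats::setNames(proj_top,
                                                        c("top1", "top2",
                                                          "top3")))
  class(out) <- c("ventile_report", "data.frame")
  attr(out, "top") <- top
  attr(out, "model") <- label
  attr(out, "labels") <- v
  out
}

#' @export
#' @method print ventile_report
print.ventile_report <- function(x, ...) {
  cat(sprintf("Ventile report for model %s\n", attr(x, "model")))
  top <- attr(x, "top")
  cat(sprintf("  top ventile: %.1f%% of cases, observed PPV %.1f/1000 pm, projected %.1f/1000 at horizon\n",
              top["concentration_pct", "top1"],
              top["observed_ppv_per_1000pm", "top1"],
              top["projected_ppv_per_1000", "top1"]))
  cat(sprintf("  top three:   %.1f%% of cases\n",
              top["concentration_pct", "top3"]))
  invisible(x)
}
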