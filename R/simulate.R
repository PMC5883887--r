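#' Simulate a synthetic cohort skeleton
#'
#' Draws subjects, sampling clusters, survey weights, latent risks, and
#' the censoring schedule (attrition and administrative cutoff).  Scores
#' and events are added by [simulate_scores()] and [simulate_events()];
#' [simulate_study()] runs all three stages.
#'
#' The subject table is a `data.frame` with one row per subject and
#' columns `subject_id`, `cluster_id`, `weight`, `latent_risk`,
#' `static_score` (NA until scores are simulated), `event_month` (NA
#' until events are simulated), `last_observed_month`, `censor_reason`.
#' Monthly scores live in a long-format companion table accessible via
#' [score_table()].
#'
#' @param config a [sim_config()].
#' @return a subject table (`data.frame`, class `subject_table`).
#' @export
simulate_cohort <- function(config) {
  stage_seed(config$seed, 1L)
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_subjects
  if (n == 0L) {
    out <- data.frame(subject_id = integer(0), cluster_id = integer(0),
                      weight = numeric(0), latent_risk = numeric(0),
                      static_score = numeric(0), event_month = integer(0),
                      last_observed_month = integer(0),
                      censor_reason = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("subject_table", "data.frame")
    attr(out, "config") <- cfg
    return(out)
  }
  # cluster sizes uniform in range, remainder spread one subject at a time
  sz <- sample(seq(cfg$cluster_size_range[1], cfg$cluster_size_range[2]),
               cfg$n_clusters, replace = TRUE)
  short <- n - sum(sz)
  if (short > 0) {
    bump <- sample.int(cfg$n_clusters, short, replace = TRUE)
    sz <- sz + tabulate(bump, nbins = cfg$n_clusters)
  }
  cluster_id <- rep.int(seq_len(cfg$n_clusters), sz)[seq_len(n)]
  w <- exp(stats::rnorm(n, 0, cfg$weight_sd))
  w <- w / mean(w)
  u <- stats::rnorm(n)
  # months observed before attrition (>= 1; everyone observes month 0)
  t_attr <- if (cfg$attrition_monthly > 0) {
    1L + stats::rgeom(n, cfg$attrition_monthly)
  } else rep.int(.Machine$integer.max, n)
  cutoff <- sample(seq(cfg$admin_cutoff_range[1], cfg$admin_cutoff_range[2]),
                   n, replace = TRUE)
  months_obs <- pmin(t_attr, cutoff)
  out <- data.frame(
    subject_id = seq_len(n),
    cluster_id = cluster_id,
    weight = w,
    latent_risk = u,
    static_score = NA_real_,
    event_month = NA_integer_,
    last_observed_month = as.integer(months_obs - 1L),
    censor_reason = ifelse(t_attr <= cutoff, "attrition", "admin_cutoff"),
    stringsAsFactors = FALSE)
  class(out) <- c("subject_table", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' Monthly score table of a cohort
#'
#' @param subjects a subject table produced by [simulate_scores()].
#' @return long-format `data.frame` with columns `subject_id`, `month`,
#'   `score_A`.
#' @export
score_table <- function(subjects) {
  st <- attr(subjects, "scores")
  if (is.null(st)) stop("cohort has no monthly scores; run simulate_scores()",
                        call. = FALSE)
  st
}

#' Simulate the two composite risk scores
#'
#' Adds the static survey score `S = lambda_S u + sqrt(1 - lambda_S^2) e`
#' and the monthly administrative score
#' `A_m = lambda_A(m) u + sqrt(1 - lambda_A(m)^2) eps_m`, where `u` is the
#' latent risk and `eps_m` is a stationary AR(1) process with unit
#' marginal variance.  Both scores are marginally standard normal by
#' construction, and their within-month correlation is
#' `lambda_S * lambda_A(m)`.
#'
#' @param subjects a subject table from [simulate_cohort()].
#' @param config the same [sim_config()].
#' @return the subject table with `static_score` filled and the monthly
#'   score table attached (see [score_table()]).
#' @export
simulate_scores <- function(subjects, config) {
  validate_sim_config(config)
  cfg <- config
  if (is.null(subjects$latent_risk)) {
    stop("subjects lack latent risks; run simulate_cohort() first",
         call. = FALSE)
  }
  n <- nrow(subjects)
  if (n == 0L) {
    attr(subjects, "scores") <- data.frame(subject_id = integer(0),
                                           month = integer(0),
                                           score_A = numeric(0))
    return(subjects)
  }
  stage_seed(cfg$seed, 2L)
  u <- subjects$latent_risk
  subjects$static_score <-
    cfg$lambda_S * u + sqrt(1 - cfg$lambda_S^2) * stats::rnorm(n)
  max_m <- max(subjects$last_observed_month)
  months <- 0:max_m
  lamA <- lambda_A_at(cfg, months)
  # AR(1) idiosyncratic part, unit marginal variance, n x (max_m + 1)
  eps <- matrix(0, n, max_m + 1L)
  eps[, 1] <- stats::rnorm(n)
  if (max_m >= 1L) {
    innov_sd <- sqrt(1 - cfg$ar_phi^2)
    for (m in seq_len(max_m)) {
      eps[, m + 1L] <- cfg$ar_phi * eps[, m] +
        innov_sd * stats::rnorm(n)
    }
  }
  A <- outer(u, lamA) + sweep(eps, 2, sqrt(1 - lamA^2), `*`)
  keep <- outer(subjects$last_observed_month, months, `>=`)
  idx <- which(keep, arr.ind = TRUE)
  scores <- data.frame(subject_id = subjects$subject_id[idx[, 1]],
                       month = months[idx[, 2]],
                       score_A = A[idx])
  scores <- scores[order(scores$subject_id, scores$month), , drop = FALSE]
  rownames(scores) <- NULL
  attr(subjects, "scores") <- scores
  subjects
}

#' Simulate first-occurrence events
#'
#' For each subject and observed month an event is drawn with probability
#' `plogis(alpha_m + beta_A A_im + beta_S(m) S_i)`, where `alpha_m`
#' includes the training offset during the first `training_months`
#' months.  The first event ends the subject's series: follow-up and
#' monthly scores are truncated at the event month and `censor_reason`
#' becomes `"event"`.
#'
#' @param subjects a subject table with scores (see [simulate_scores()]).
#' @param config the same [sim_config()].
#' @return the subject table with `event_month` and truncated follow-up.
#' @export
simulate_events <- function(subjects, config) {
  validate_sim_config(config)
  cfg <- config
  if (nrow(subjects) == 0L) return(subjects)
  if (all(is.na(subjects$static_score))) {
    stop("subjects lack scores; run simulate_scores() first", call. = FALSE)
  }
  scores <- score_table(subjects)
  stage_seed(cfg$seed, 3L)
  m <- scores$month
  row_of <- match(scores$subject_id, subjects$subject_id)
  eta <- alpha_at(cfg, m) + cfg$beta_A * scores$score_A +
    beta_S_at(cfg, m) * subjects$static_score[row_of]
  hit <- stats::runif(nrow(scores)) < stats::plogis(eta)
  # first event month per subject (scores are sorted by subject, month)
  hidx <- which(hit)
  first <- hidx[!duplicated(row_of[hidx])]
  ev <- rep(NA_integer_, nrow(subjects))
  ev[row_of[first]] <- m[first]
  has_ev <- !is.na(ev)
  subjects$event_month <- ev
  subjects$last_observed_month[has_ev] <-
    pmin(subjects$last_observed_month[has_ev], ev[has_ev])
  subjects$censor_reason[has_ev] <- "event"
  keep <- scores$month <= subjects$last_observed_month[row_of]
  attr(subjects, "scores") <- scores[keep, , drop = FALSE]
  subjects
}

#' Simulate a complete study cohort
#'
#' Convenience wrapper running [simulate_cohort()], [simulate_scores()]
#' and [simulate_events()] in sequence.
#'
#' @param config a [sim_config()].
#' @return a subject table with scores and events.
#' @export
simulate_study <- function(config) {
  simulate_events(simulate_scores(simulate_cohort(config), config), config)
}

#' @export
#' @method print subject_table
print.subject_table <- function(x, ...) {
  cat(sprintf(
    "Subject table: %d subjects, %d clusters, %d events\n",
    nrow(x), length(unique(x$cluster_id)), sum(!is.na(x$event_month))))
  NextMethod()
}

#' Write / read a cohort as flat delimited tables
#'
#' Writes the one-row-per-subject table, the long-format monthly score
#' table, and a plain-text metadata sidecar (configuration and seed,
#' Debian-control format).  `read_cohort()` restores the cohort
#' losslessly up to numeric printing precision (full 17 significant
#' digits are written).
#'
#' @param subjects a subject table.
#' @param path directory to write into (created if missing).
#' @return `write_cohort()` returns the paths invisibly; `read_cohort()`
#'   returns a subject table.
#' @export
write_cohort <- function(subjects, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fs <- file.path(path, c("subjects.tsv", "scores.tsv", "metadata.dcf"))
  subj <- as.data.frame(subjects)
  old <- options(digits = 17); on.exit(options(old))
  utils::write.table(subj, fs[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(attr(subjects, "scores"), fs[2], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- attr(subjects, "config")
  if (!is.null(cfg)) {
    meta <- lapply(unclass(cfg), function(v) paste(format(v, digits = 17),
                                                   collapse = " "))
    write.dcf(as.data.frame(meta, stringsAsFactors = FALSE), fs[3])
  }
  invisible(fs)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  subj <- utils::read.table(file.path(path, "subjects.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  class(subj) <- c("subject_table", "data.frame")
  sf <- file.path(path, "scores.tsv")
  if (file.exists(sf)) {
    attr(subj, "scores") <- utils::read.table(sf, sep = "\t", header = TRUE,
                                              stringsAsFactors = FALSE)
  }
  subj
}

# per-stage substreams: scrambling through a seeded draw keeps nearby master
# seeds (and the three stages of one run) statistically unrelated
stage_seed <- function(seed, stage) {
  set.seed(seed)
  set.seed(sample.int(.Machine$integer.max - 1L, 3L)[stage])
}
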