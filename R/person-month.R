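#' Survey design information
#'
#' A light container for the design variables of a single-stage cluster
#' sample: one weight and one sampling-cluster label per subject, with an
#' optional stratum label.  Most functions in the package read the design
#' directly from the `weight` / `cluster_id` columns of the subject table
#' or person-month array; an explicit `survey_design` can be supplied to
#' override them.
#'
#' @param subject_id subject identifiers.
#' @param weight positive survey weights.
#' @param cluster_id sampling-cluster labels.
#' @param stratum optional stratum labels.
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(subject_id, weight, cluster_id, stratum = NULL) {
  if (length(weight) != length(subject_id) ||
      length(cluster_id) != length(subject_id)) {
    stop("subject_id, weight and cluster_id must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("all weights must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(subject_id)) {
    stop("every subject must have exactly one weight and cluster",
         call. = FALSE)
  }
  structure(list(subject_id = subject_id, weight = weight,
                 cluster_id = cluster_id, stratum = stratum),
            class = "survey_design")
}

# apply an explicit design (if any) onto a table holding subject_id
apply_design <- function(tab, design) {
  if (is.null(design)) return(tab)
  stopifnot(inherits(design, "survey_design"))
  i <- match(tab$subject_id, design$subject_id)
  if (anyNA(i)) stop("design does not cover all subjects", call. = FALSE)
  tab$weight <- design$weight[i]
  tab$cluster_id <- design$cluster_id[i]
  tab
}

#' Expand subjects into the discrete-time person-month array
#'
#' The person-month array is the backbone of the analysis: one row per
#' subject per month at risk, with month 0 the survey month.  The event
#' month is included as an at-risk row and carries the only `event = 1`
#' flag of its subject; follow-up ends at the first occurrence, service
#' termination, or the administrative cutoff, whichever comes first.
#'
#' @param subjects a subject table (see [simulate_study()] or
#'   [read_cohort()]).
#' @param design optional [survey_design()] overriding the table's
#'   `weight` / `cluster_id` columns.
#' @return a `data.frame` of class `person_month` with columns
#'   `subject_id`, `month`, `score_A`, `score_S`, `event`, `weight`,
#'   `cluster_id`.
#' @export
expand_person_months <- function(subjects, design = NULL) {
  subjects <- apply_design(subjects, design)
  bad <- !is.na(subjects$event_month) &
    subjects$event_month > subjects$last_observed_month
  if (any(bad)) {
    stop("event_month exceeds last_observed_month for subject(s) ",
         paste(utils::head(subjects$subject_id[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(subjects$last_observed_month < 0)) {
    stop("last_observed_month must be >= 0", call. = FALSE)
  }
  # follow-up ends at the first occurrence: the event row is the last row
  eff_last <- ifelse(is.na(subjects$event_month),
                     subjects$last_observed_month,
                     pmin(subjects$event_month,
                          subjects$last_observed_month))
  n_rows <- eff_last + 1L
  i <- rep.int(seq_len(nrow(subjects)), n_rows)
  month <- sequence(n_rows) - 1L
  out <- data.frame(
    subject_id = subjects$subject_id[i],
    month = month,
    score_A = NA_real_,
    score_S = subjects$static_score[i],
    event = as.integer(!is.na(subjects$event_month[i]) &
                         month == subjects$event_month[i]),
    weight = subjects$weight[i],
    cluster_id = subjects$cluster_id[i],
    stringsAsFactors = FALSE)
  st <- attr(subjects, "scores")
  if (!is.null(st)) {
    # integer keys (subject index, month) are much faster than paste()
    K <- max(out$month, st$month) + 2
    sub_idx <- match(st$subject_id, subjects$subject_id)
    key <- match(as.numeric(i) * K + out$month,
                 as.numeric(sub_idx) * K + st$month)
    out$score_A <- st$score_A[key]
  }
  class(out) <- c("person_month", "data.frame")
  out
}

#' @export
#' @method print person_month
print.person_month <- function(x, ...) {
  cat(sprintf("Person-month array: %d rows, %d subjects, %d events\n",
              nrow(x), length(unique(x$subject_id)), sum(x$event)))
  NextMethod()
}

# weighted first/second moments (population form)
weighted_moments <- function(x, w) {
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)
  c(mean = m, var = v)
}

#' Standardize the composite scores
#'
#' Rescales each score to weighted mean 0 and weighted variance 1.  The
#' monthly administrative score `A` is standardized over person-month
#' rows (it varies monthly); the static survey score `S` is standardized
#' over subjects, so each subject keeps a single standardized value.
#'
#' @param array a person-month array ([expand_person_months()]).
#' @param design optional [survey_design()] overriding embedded weights.
#' @return the array with standardized `score_A` and `score_S`; attribute
#'   `standardized` is set to `TRUE`.
#' @export
standardize_scores <- function(array, design = NULL) {
  array <- apply_design(array, design)
  if (anyNA(array$score_A) || anyNA(array$score_S)) {
    stop("scores contain missing values", call. = FALSE)
  }
  mA <- weighted_moments(array$score_A, array$weight)
  first <- !duplicated(array$subject_id)
  mS <- weighted_moments(array$score_S[first], array$weight[first])
  if (mA["var"] <= 0) stop("score_A has zero variance", call. = FALSE)
  if (mS["var"] <= 0) stop("score_S has zero variance", call. = FALSE)
  array$score_A <- (array$score_A - mA["mean"]) / sqrt(mA["var"])
  array$score_S <- (array$score_S - mS["mean"]) / sqrt(mS["var"])
  attr(array, "standardized") <- TRUE
  array
}

#' Write / read a person-month array
#'
#' Long-format tab-delimited round trip with fixed column names
#' (`subject_id`, `month`, `score_A`, `score_S`, `event`, `weight`,
#' `cluster_id`); numeric columns are written with 17 significant digits
#' so the round trip is lossless.
#'
#' @param array a person-month array.
#' @param file path of the delimited file.
#' @return `write_person_months()` the path, invisibly;
#'   `read_person_months()` the array.
#' @export
write_person_months <- function(array, file) {
  old <- options(digits = 17); on.exit(options(old))
  utils::write.table(as.data.frame(array), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_person_months
#' @export
read_person_months <- function(file) {
  out <- utils::read.table(file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "month", "score_A", "score_S", "event",
            "weight", "cluster_id")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  class(out) <- c("person_month", "data.frame")
  out
}
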