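ALL_TERMS <- c("T", "A", "A2", "TA", "S", "S2", "TS", "AS")

#' Model specifications for the hazard-model ladder
#'
#' A model specification is a set of terms drawn from: `T` (per-month
#' dummies for time since survey, reference = earliest month), `A`
#' (monthly administrative score), `A2` (its square), `TA` (A interacted
#' with binned time: 13-24 and 25+ months), `S` (static survey score),
#' `S2`, `TS` (S interacted with binned time) and `AS` (score product).
#' The canonical ladder labels are:
#' \describe{
#'   \item{M1}{T}
#'   \item{M2}{T + A}
#'   \item{M3}{T + A + T*A}
#'   \item{M4}{T + A + A^2}
#'   \item{M5}{T + A + T*A + A^2}
#'   \item{M6}{Ba + S (Ba = best model among M1-M5)}
#'   \item{M7}{Ba + S + T*S}
#'   \item{M8}{Ba + S + S^2}
#'   \item{M9}{Ba + S + T*S + S^2}
#'   \item{M10}{Ba + S + A*S}
#'   \item{M11}{Ba + S + A*S + T*S}
#' }
#'
#' @param label one of `"M1"` ... `"M11"`, or `NULL` to pass `terms`
#'   directly.
#' @param terms character vector of terms (used when `label` is `NULL`;
#'   e.g. `c("T", "S")` for a survey-score-only model).
#' @param base label of the best administrative-score-only model `Ba`
#'   that M6-M11 extend (default `"M2"`).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(label = NULL, terms = NULL, base = "M2") {
  if (!is.null(label)) {
    base_terms <- switch(base,
      M1 = "T", M2 = c("T", "A"), M3 = c("T", "A", "TA"),
      M4 = c("T", "A", "A2"), M5 = c("T", "A", "TA", "A2"),
      stop("base must be one of M1-M5", call. = FALSE))
    terms <- switch(label,
      M1 = "T", M2 = c("T", "A"), M3 = c("T", "A", "TA"),
      M4 = c("T", "A", "A2"), M5 = c("T", "A", "TA", "A2"),
      M6 = c(base_terms, "S"),
      M7 = c(base_terms, "S", "TS"),
      M8 = c(base_terms, "S", "S2"),
      M9 = c(base_terms, "S", "TS", "S2"),
      M10 = c(base_terms, "S", "AS"),
      M11 = c(base_terms, "S", "AS", "TS"),
      stop("unknown model label ", label, call. = FALSE))
  }
  terms <- unique(terms)
  bad <- setdiff(terms, ALL_TERMS)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!"T" %in% terms) stop("every model controls for time: term T required",
                            call. = FALSE)
  need <- list(A2 = "A", TA = "A", S2 = "S", TS = "S", AS = c("A", "S"))
  for (tm in names(need)) {
    if (tm %in% terms && !all(need[[tm]] %in% terms)) {
      stop(tm, " requires main effect(s) ",
           paste(need[[tm]], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(label = if (is.null(label)) "custom" else label,
                 terms = terms[order(match(terms, ALL_TERMS))],
                 base = base),
            class = "model_spec")
}

#' @export
#' @method print model_spec
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %s: %s\n", x$label, paste(x$terms, collapse = " + ")))
  invisible(x)
}

# binned-time indicators used by the TA / TS interaction terms
bin_13_24 <- function(month) as.numeric(month >= 13 & month <= 24)
bin_25p <- function(month) as.numeric(month >= 25)

#' Build the predictor matrix of a hazard model
#'
#' Columns, in deterministic order: intercept; one dummy per month in the
#' data beyond the reference (earliest) month; then, per the
#' specification: `A`, `A2`, `A:T13_24`, `A:T25p`, `S`, `S2`,
#' `S:T13_24`, `S:T25p`, `A:S`.  Interaction time is binned (0-12
#' reference, 13-24, 25+); main-effect time has one dummy per month.
#'
#' @param array a standardized person-month array.
#' @param spec a [model_spec()].
#' @param dummy_months optional integer vector fixing the dummy basis
#'   (used when predicting from a fitted model); default derives it from
#'   the months present.
#' @param unseen what to do with months absent from `dummy_months` and
#'   not the reference: `"error"` rejects, `"reference"` codes them as
#'   the reference month (all dummies zero).
#' @return a sparse `dgCMatrix` with an attribute `term_cols` mapping
#'   each term to its column names and `dummy_months` recording the
#'   basis.
#' @export
build_design_matrix <- function(array, spec, dummy_months = NULL,
                                unseen = c("error", "reference")) {
  unseen <- match.arg(unseen)
  stopifnot(inherits(spec, "model_spec"))
  month <- array$month
  if (any(month < 0)) stop("negative months are not representable",
                           call. = FALSE)
  months_here <- sort(unique(month))
  if (is.null(dummy_months)) {
    dummy_months <- months_here[-1L]
  } else {
    # months outside the basis are reference-coded; with unseen = "error"
    # only a single reference month is tolerated
    outside <- setdiff(months_here, dummy_months)
    if (unseen == "error" && length(outside) > 1L) {
      stop("months present but not representable in dummy basis: ",
           paste(outside[-1L], collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(array)
  i_list <- list()
  x_list <- list()
  names_out <- character(0)
  add_col <- function(name, rows, vals) {
    i_list[[length(i_list) + 1L]] <<- rows
    x_list[[length(x_list) + 1L]] <<- vals
    names_out[length(names_out) + 1L] <<- name
  }
  add_dense <- function(name, v) {
    nz <- which(v != 0)
    add_col(name, nz, v[nz])
  }
  add_col("(Intercept)", seq_len(n), rep.int(1, n))
  for (m in dummy_months) {
    rows <- which(month == m)
    add_col(paste0("T", m), rows, rep.int(1, length(rows)))
  }
  A <- array$score_A
  S <- array$score_S
  b1 <- bin_13_24(month)
  b2 <- bin_25p(month)
  tm <- spec$terms
  if ("A" %in% tm) add_dense("A", A)
  if ("A2" %in% tm) add_dense("A2", A^2)
  if ("TA" %in% tm) {
    add_dense("A:T13_24", A * b1)
    add_dense("A:T25p", A * b2)
  }
  if ("S" %in% tm) add_dense("S", S)
  if ("S2" %in% tm) add_dense("S2", S^2)
  if ("TS" %in% tm) {
    add_dense("S:T13_24", S * b1)
    add_dense("S:T25p", S * b2)
  }
  if ("AS" %in% tm) add_dense("A:S", A * S)
  lens <- lengths(i_list)
  ii <- unlist(i_list, use.names = FALSE)
  jj <- rep.int(seq_along(i_list), lens)
  xx <- unlist(x_list, use.names = FALSE)
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, length(i_list)),
                            dimnames = list(NULL, names_out))
  tc <- list(T = paste0("T", dummy_months))
  if ("A" %in% tm) tc$A <- "A"
  if ("A2" %in% tm) tc$A2 <- "A2"
  if ("TA" %in% tm) tc$TA <- c("A:T13_24", "A:T25p")
  if ("S" %in% tm) tc$S <- "S"
  if ("S2" %in% tm) tc$S2 <- "S2"
  if ("TS" %in% tm) tc$TS <- c("S:T13_24", "S:T25p")
  if ("AS" %in% tm) tc$AS <- "A:S"
  attr(X, "term_cols") <- tc
  attr(X, "dummy_months") <- dummy_months
  X
}
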