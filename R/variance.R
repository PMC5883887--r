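#' Design-based (Taylor linearization) cluster sandwich covariance
#'
#' Variance of the weighted maximum-likelihood coefficients honoring the
#' survey design: score contributions `w_i (y_i - mu_i) x_i` are summed
#' within sampling clusters, outer-producted across clusters
#' (with-replacement first-stage assumption), scaled by the small-sample
#' factor `c / (c - 1)` with `c` the number of clusters, and wrapped in
#' the inverse observed information ("bread"):
#' `V = A^{-1} B A^{-1}`.  With one subject per cluster and equal
#' weights this reduces to the ordinary heteroskedasticity-robust
#' sandwich, and it is invariant to rescaling all weights by a constant.
#'
#' @param fit a `hazard_fit` (must have converged).
#' @param array,design optional person-month array and/or
#'   [survey_design()] supplying alternative cluster labels; by default
#'   the clusters stored in the fit are used.
#' @param cadjust apply the `c/(c-1)` small-sample cluster correction
#'   (default `TRUE`).
#' @return symmetric covariance matrix with coefficient dimnames.
#' @export
sandwich_covariance <- function(fit, array = NULL, design = NULL,
                                cadjust = TRUE) {
  stopifnot(inherits(fit, "hazard_fit"))
  if (!fit$converged) {
    stop("fit did not converge; covariance would be unreliable",
         call. = FALSE)
  }
  cluster <- fit$cluster
  if (!is.null(design)) {
    stopifnot(inherits(design, "survey_design"))
    i <- match(fit$subject_id, design$subject_id)
    if (anyNA(i)) stop("design does not cover all subjects", call. = FALSE)
    cluster <- design$cluster_id[i]
  } else if (!is.null(array)) {
    i <- match(fit$subject_id, array$subject_id)
    cluster <- array$cluster_id[i]
  }
  cl <- factor(cluster)
  nc <- nlevels(cl)
  if (nc < 2L) {
    stop("variance undefined with a single sampling cluster", call. = FALSE)
  }
  resid <- fit$w * (fit$y - fit$mu)
  U <- resid * fit$X                      # n x p score contributions
  M <- Matrix::sparseMatrix(i = as.integer(cl), j = seq_along(resid),
                            x = 1, dims = c(nc, length(resid)))
  G <- M %*% U                            # cluster-summed scores, c x p
  meat <- as.matrix(Matrix::crossprod(G))
  if (cadjust) meat <- meat * nc / (nc - 1)
  wirls <- fit$w * fit$mu * (1 - fit$mu)
  A <- as.matrix(Matrix::crossprod(sqrt(wirls) * fit$X))
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) MASS_ginv(A))
  V <- Ainv %*% meat %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(fit$coefficients), names(fit$coefficients))
  V
}

#' Design-based Wald chi-square test of a coefficient block
#'
#' Tests `H0: beta_block = 0` with the quadratic form
#' `chi^2 = beta' V^{-1} beta` on the block's design-based covariance
#' submatrix; degrees of freedom equal the block size.
#'
#' @param fit a `hazard_fit` with a design-based covariance (or
#'   `vcov = "model"` for the model-based test).
#' @param block terms (e.g. `"S"`, `"TS"`) and/or coefficient names
#'   identifying the tested block.
#' @param vcov which covariance to use.
#' @return object of class `wald_test` with `statistic`, `df`, `p_value`
#'   and `block`.
#' @export
wald_test <- function(fit, block, vcov = c("design", "model")) {
  vcov <- match.arg(vcov)
  stopifnot(inherits(fit, "hazard_fit"))
  cols <- unlist(lapply(block, function(b) {
    if (b %in% names(fit$term_cols)) fit$term_cols[[b]] else b
  }), use.names = FALSE)
  bad <- setdiff(cols, names(fit$coefficients))
  if (length(bad)) stop("unknown coefficient(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  b <- fit$coefficients[cols]
  V <- vcov.hazard_fit(fit, vcov)[cols, cols, drop = FALSE]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    stop("covariance submatrix of the tested block is singular",
         call. = FALSE)
  }
  stat <- drop(crossprod(backsolve(ch, b, transpose = TRUE)))
  df <- length(b)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 block = cols, terms = block),
            class = "wald_test")
}

#' @export
#' @method print wald_test
print.wald_test <- function(x, ...) {
  cat(sprintf("Design-based Wald test of {%s}: chi2(%d) = %.2f, p = %.4g\n",
              paste(x$terms, collapse = ", "), x$df, x$statistic,
              x$p_value))
  invisible(x)
}

#' Compare nested hazard models
#'
#' Wald test of the terms the larger model adds over the smaller one,
#' evaluated within the larger fit (the design-based analogue of an
#' added-block test; not a likelihood-ratio test).
#'
#' @param fit_small,fit_large nested `hazard_fit` objects (the smaller
#'   specification's terms must be a strict subset of the larger's).
#' @param vcov which covariance to use.
#' @return a `wald_test` of the added block, with an extra `comparison`
#'   element naming the two models.
#' @export
compare_nested <- function(fit_small, fit_large,
                           vcov = c("design", "model")) {
  stopifnot(inherits(fit_small, "hazard_fit"),
            inherits(fit_large, "hazard_fit"))
  small <- fit_small$spec$terms
  large <- fit_large$spec$terms
  if (!all(small %in% large)) {
    stop("models are not nested: smaller model has term(s) ",
         paste(setdiff(small, large), collapse = ", "),
         " absent from the larger model", call. = FALSE)
  }
  added <- setdiff(large, small)
  if (!length(added)) {
    stop("specifications are identical; nothing to test", call. = FALSE)
  }
  out <- wald_test(fit_large, added, vcov = match.arg(vcov))
  out$comparison <- paste0(fit_large$spec$label, "-", fit_small$spec$label)
  out
}
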