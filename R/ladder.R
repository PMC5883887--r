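#' Run the nested model-selection ladder
#'
#' Two-step design-based model selection for combining the two composite
#' risk scores.  Step 1 finds the best administrative-score-only model:
#' starting from `M2` (time + A), the binned time interaction `T*A`
#' (`M3-M2`) and the quadratic `A^2` (`M4-M2`) are block-tested at level
#' `alpha`; significant blocks are retained (both significant selects
#' `M5`).  If even the `A` main effect is non-significant the base falls
#' back to `M1`.  Step 2 adds the survey score `S` to the selected base
#' (`M6`) and, when `S` is significant, tests `T*S` (`M7-M6`) and `S^2`
#' (`M8-M6`) the same way.  The score-product interaction `A*S`
#' (`M10`/`M11`) is fitted and tested only when step 2 selected an
#' interaction or quadratic extension, mirroring the published strategy
#' in which the product term was examined only for the outcome whose
#' best model contained `T*S`.
#'
#' @param array a standardized person-month array with both scores.
#' @param design optional [survey_design()].
#' @param alpha significance level for block retention (default 0.05).
#' @param fit_args extra arguments passed to [fit_hazard_model()].
#' @return an object of class `model_ladder`: `fits` (named list of
#'   `hazard_fit`s), `tests` (difference-test table mirroring the model
#'   comparison layout: comparison, added block, df, chi-square, p),
#'   `model_tests` (per-model Wald test of all non-time terms), `base`
#'   (selected administrative-only label), `selected` (final label),
#'   `selected_fit`, and `alpha`.
#' @export
run_model_ladder <- function(array, design = NULL, alpha = 0.05,
                             fit_args = list()) {
  if (sum(array$event) == 0L) {
    stop("no events in the person-month array", call. = FALSE)
  }
  array <- apply_design(array, design)
  fits <- list()
  do_fit <- function(label, base = "M2") {
    do.call(fit_hazard_model,
            c(list(array = array, spec = model_spec(label, base = base)),
              fit_args))
  }
  tests <- list()
  add_test <- function(small, large) {
    wt <- compare_nested(fits[[small]], fits[[large]])
    tests[[length(tests) + 1L]] <<- data.frame(
      comparison = paste0(large, "-", small),
      block = paste(setdiff(fits[[large]]$spec$terms,
                            fits[[small]]$spec$terms), collapse = "+"),
      df = wt$df, chisq = wt$statistic, p = wt$p_value,
      stringsAsFactors = FALSE)
    wt$p_value
  }

  for (lab in c("M1", "M2", "M3", "M4", "M5")) fits[[lab]] <- do_fit(lab)
  p_A <- add_test("M1", "M2")
  p_TA <- add_test("M2", "M3")
  p_A2 <- add_test("M2", "M4")
  add_test("M4", "M5")   # T*A given A^2
  add_test("M3", "M5")   # A^2 given T*A
  base <- if (p_A >= alpha) "M1"
          else if (p_TA < alpha && p_A2 < alpha) "M5"
          else if (p_TA < alpha) "M3"
          else if (p_A2 < alpha) "M4"
          else "M2"

  for (lab in c("M6", "M7", "M8", "M9")) fits[[lab]] <- do_fit(lab, base)
  p_S <- {
    wt <- compare_nested(fits[[base]], fits[["M6"]])
    tests[[length(tests) + 1L]] <- data.frame(
      comparison = paste0("M6-", base), block = "S", df = wt$df,
      chisq = wt$statistic, p = wt$p_value, stringsAsFactors = FALSE)
    wt$p_value
  }
  p_TS <- add_test("M6", "M7")
  p_S2 <- add_test("M6", "M8")
  add_test("M8", "M9")   # T*S given S^2
  add_test("M7", "M9")   # S^2 given T*S
  if (p_S >= alpha) {
    selected <- base
  } else if (p_TS < alpha && p_S2 < alpha) {
    selected <- "M9"
  } else if (p_TS < alpha) {
    selected <- "M7"
  } else if (p_S2 < alpha) {
    selected <- "M8"
  } else {
    selected <- "M6"
  }
  if (selected %in% c("M7", "M8", "M9") &&
      "A" %in% fits[[base]]$spec$terms) {
    fits[["M10"]] <- do_fit("M10", base)
    fits[["M11"]] <- do_fit("M11", base)
    add_test("M10", "M11")   # T*S given A*S
    p_AS <- add_test("M7", "M11")
    if (selected == "M7" && p_AS < alpha) selected <- "M11"
  }

  tests <- do.call(rbind, tests)
  model_tests <- do.call(rbind, lapply(names(fits), function(lab) {
    fit <- fits[[lab]]
    terms <- setdiff(fit$spec$terms, "T")
    if (!length(terms)) {
      return(data.frame(model = lab, df = NA_integer_, chisq = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    wt <- wald_test(fit, terms)
    data.frame(model = lab, df = wt$df, chisq = wt$statistic,
               p = wt$p_value, stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, tests = tests, model_tests = model_tests,
                 base = base, selected = selected,
                 selected_fit = fits[[selected]], alpha = alpha),
            class = "model_ladder")
}

#' @export
#' @method print model_ladder
print.model_ladder <- function(x, ...) {
  cat("Discrete-time hazard model ladder\n")
  cat(sprintf("  base (administrative-only) model: %s; selected: %s (alpha = %.3g)\n",
              x$base, x$selected, x$alpha))
  cat("  model differences:\n")
  t <- x$tests
  for (i in seq_len(nrow(t))) {
    cat(sprintf("    %-8s %-6s df=%d  chi2=%8.2f  p=%.4g\n",
                t$comparison[i], t$block[i], t$df[i], t$chisq[i], t$p[i]))
  }
  invisible(x)
}
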