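#' Configuration of a full pipeline run
#'
#' @param preset outcome preset name (see [outcome_preset()]) or
#'   `"custom"` to build the simulator configuration entirely from
#'   `sim_overrides`.
#' @param sim_overrides named list of [sim_config()] fields overriding
#'   the preset (for `"custom"`, the full argument list of
#'   [sim_config()]).
#' @param alpha significance level of the model-selection ladder.
#' @param horizon projection horizon in months (<= 44; evaluation uses
#'   36).
#' @param seed root seed; all stage randomness derives from it.
#' @param ranking per-person ranking method (see
#'   [person_risk_summary()]).
#' @param weighted use survey weights in the correlation series.
#' @return a `run_config` object.
#' @export
run_config <- function(preset = c("victimization", "physical_perpetration",
                                  "sexual_perpetration", "custom"),
                       sim_overrides = list(), alpha = 0.05,
                       horizon = 36L, seed = 1L,
                       ranking = c("cumulative", "mean_log_odds"),
                       weighted = TRUE) {
  preset <- match.arg(preset)
  if (horizon > 44L) stop("horizon must be at most 44 months",
                          call. = FALSE)
  structure(list(preset = preset, sim_overrides = sim_overrides,
                 alpha = alpha, horizon = as.integer(horizon),
                 seed = as.integer(seed), ranking = match.arg(ranking),
                 weighted = weighted),
            class = "run_config")
}

resolve_sim_config <- function(config) {
  if (config$preset == "custom") {
    do.call(sim_config, c(config$sim_overrides, list(seed = config$seed)))
  } else {
    cfg <- outcome_preset(config$preset, seed = config$seed)
    if (length(config$sim_overrides)) {
      for (f in names(config$sim_overrides)) {
        cfg[[f]] <- config$sim_overrides[[f]]
      }
      validate_sim_config(cfg)
    }
    cfg
  }
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Sequences the whole analysis: simulate a cohort, expand it to the
#' person-month array and standardize the scores, compute the
#' within-month correlation series and its summaries, run the
#' model-selection ladder, and evaluate the administrative-only,
#' survey-only and best-fitting models by ventile (concentration of
#' risk, observed and projected PPV, proportional improvements), plus
#' the actuarial life table, morbid risk and months-to-occurrence
#' summary.  Any stage failure aborts with the stage name and cause.
#'
#' @param config a [run_config()].
#' @return an object of class `report_bundle`; see the elements listed
#'   under Details in the package vignette.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  note <- function(...) log <<- c(log, sprintf(...))
  sim_cfg <- stage("configure", resolve_sim_config(config))
  note("configure: preset %s, n=%d, seed=%d, alpha=%.3g, ranking=%s",
       config$preset, sim_cfg$n_subjects, config$seed, config$alpha,
       config$ranking)
  subjects <- stage("simulate", simulate_study(sim_cfg))
  note("simulate: %d subjects, %d events", nrow(subjects),
       sum(!is.na(subjects$event_month)))
  array <- stage("expand", standardize_scores(
    expand_person_months(subjects)))
  note("expand: %d person-month rows", nrow(array))
  correlations <- stage("correlate",
                        within_month_correlations(array,
                                                  weighted = config$weighted))
  corr_summary <- summarize_series(correlations)
  corr_trend <- trend_correlation(correlations)
  note("correlate: median within-month r = %.3f, trend r = %.3f",
       corr_summary["median"], corr_trend)
  ladder <- stage("ladder", run_model_ladder(array, alpha = config$alpha))
  note("ladder: base %s, selected %s", ladder$base, ladder$selected)
  nss_spec <- model_spec(terms = c("T", "S"))
  nss_spec$label <- "NSS-only"
  fit_nss <- stage("ladder", fit_hazard_model(array, nss_spec))
  models <- list(hads_only = ladder$fits[[ladder$base]],
                 nss_only = fit_nss,
                 best = ladder$selected_fit)
  reports <- stage("evaluate", lapply(names(models), function(nm) {
    ventile_report(models[[nm]], subjects, array,
                   horizon = min(config$horizon, 36L),
                   method = config$ranking, label = nm)
  }))
  names(reports) <- names(models)
  improvements <- do.call(rbind, lapply(
    rownames(attr(reports$best, "top")), function(metric) {
      data.frame(metric = metric,
                 ventiles = 1:3,
                 hads_only = attr(reports$hads_only, "top")[metric, ],
                 best = attr(reports$best, "top")[metric, ],
                 improvement_pct = proportional_improvement(
                   attr(reports$best, "top")[metric, ],
                   attr(reports$hads_only, "top")[metric, ]),
                 stringsAsFactors = FALSE)
    }))
  rownames(improvements) <- NULL
  lt <- stage("actuarial", life_table(subjects,
                                      horizon = min(config$horizon, 36L)))
  mr <- morbid_risk(lt, min(config$horizon, 36L))
  ev_q <- stage("actuarial", median_iqr_event_time(subjects))
  note("evaluate: morbid risk %.1f/1000 at %d months; best top-ventile concentration %.1f%%",
       mr, min(config$horizon, 36L),
       attr(reports$best, "top")["concentration_pct", "top1"])
  structure(list(config = config, sim_config = sim_cfg,
                 subjects = subjects, array = array,
                 correlations = correlations,
                 corr_summary = corr_summary, corr_trend = corr_trend,
                 ladder = ladder, models = models, reports = reports,
                 improvements = improvements, life_table = lt,
                 morbid_risk = mr, event_time_quantiles = ev_q,
                 log = log),
            class = "report_bundle")
}

#' @export
#' @method print report_bundle
print.report_bundle <- function(x, ...) {
  cat("Pipeline report bundle\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Writes fixed-schema tab-delimited tables: the correlation series, the
#' model-ladder fit and difference tests, the best model's coefficient
#' table, the per-ventile performance of the three evaluated models, the
#' top-ventile summary with proportional improvements, the life table,
#' and a manifest listing each file with its row count and MD5 checksum.
#' On failure, partially written files are removed.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param outdir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_tables <- function(bundle, outdir) {
  if (!inherits(bundle, "report_bundle") || is.null(bundle$reports)) {
    stop("bundle is not a complete report_bundle", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir,
                                call. = FALSE)
  old <- options(digits = 17); on.exit(options(old))
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("write_tables failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    put <- function(df, name) {
      f <- file.path(outdir, name)
      utils::write.table(df, f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      written <<- c(written, f)
      f
    }
    put(as.data.frame(bundle$correlations), "correlation_series.tsv")
    put(bundle$ladder$model_tests, "model_fit_tests.tsv")
    put(bundle$ladder$tests, "model_differences.tsv")
    put(coef_table(bundle$models$best), "best_model_coefficients.tsv")
    vent <- do.call(rbind, lapply(names(bundle$reports), function(nm) {
      cbind(model = nm, as.data.frame(bundle$reports[[nm]]))
    }))
    put(vent, "ventile_performance.tsv")
    put(bundle$improvements, "performance_summary.tsv")
    put(as.data.frame(bundle$life_table), "survival_curve.tsv")
    manifest <- data.frame(
      file = basename(written),
      rows = vapply(written, function(f) length(readLines(f)) - 1L,
                    integer(1)),
      md5 = unname(tools::md5sum(written)),
      stringsAsFactors = FALSE)
    put(manifest, "manifest.tsv")
    invisible(stats::setNames(written, basename(written)))
  }, error = on_fail)
}
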