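# End-to-end orchestration: simulate (or load) -> preprocess -> code ->
# step -> fit -> regress -> report, as one reproducible call. Every stage
# is an exported function of its own; run_pipeline() only sequences them
# and writes the output bundle.

.PIPELINE_FIELDS <- c("mode", "out_dir", "seed", "cohort", "process", "manifest",
                      "window_s", "interval_filter", "filter_s", "bins",
                      "measures", "fit_params", "glmm_steps", "min_steps")

#' Configure a pipeline run
#'
#' A validated, fully serialisable bundle of every convention the pipeline
#' uses; a config plus its seed reproduces all outputs. Unknown fields are
#' rejected before any computation.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"load"`
#'   (read a cohort manifest).
#' @param out_dir output directory for the bundle.
#' @param seed master seed (simulate mode).
#' @param cohort a [cohort_spec()] (simulate mode).
#' @param process a [process_spec()] (simulate mode).
#' @param manifest path to a cohort manifest CSV (load mode).
#' @param window_s response window (s).
#' @param interval_filter `"gt"` or `"ge"` retention convention for split
#'   analyses.
#' @param filter_s retention threshold (s).
#' @param bins histogram bins for the R-squared diagnostic.
#' @param measures step measures to analyse.
#' @param fit_params fit families / parameter dvs in the summary stage.
#' @param glmm_steps also fit the logistic models with preceding-step
#'   predictors.
#' @param min_steps minimum retained steps per summary cell.
#' @param ... rejected; present so that misspelled arguments error.
#' @return object of class `vf_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), out_dir = tempfile("vf_run_"),
                            seed = 1L, cohort = cohort_spec(), process = process_spec(),
                            manifest = NULL, window_s = 1.0,
                            interval_filter = c("gt", "ge"), filter_s = 1.0,
                            bins = 50, measures = .STEP_MEASURES,
                            fit_params = TRUE, glmm_steps = FALSE,
                            min_steps = 5, ...) {
  extra <- list(...)
  if (length(extra)) {
    vf_stop("unknown pipeline option(s): %s", paste(names(extra), collapse = ", "))
  }
  mode <- match.arg(mode)
  interval_filter <- match.arg(interval_filter)
  if (mode == "load" && is.null(manifest)) vf_stop("load mode requires a manifest path")
  stopifnot(all(measures %in% .STEP_MEASURES))
  cfg <- list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
              cohort = cohort, process = process, manifest = manifest,
              window_s = window_s, interval_filter = interval_filter,
              filter_s = filter_s, bins = bins, measures = measures,
              fit_params = fit_params, glmm_steps = glmm_steps,
              min_steps = min_steps)
  class(cfg) <- "vf_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    vf_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocessing (unpitched removal, cohort-wide
#' standardisation), response coding, step construction, distribution
#' fitting, summary features, and the regression battery, then writes the
#' output bundle to `config$out_dir`: `events.csv`, `annotated_events.csv`,
#' `steps.csv`, `fits.csv`, `summaries.csv`, `correlations.csv`,
#' `regressions.csv`, `planted_truth.txt` (simulate mode) and
#' `run_manifest.json` (config echo, package version, seed, convention
#' flags). Identical configs and seeds produce byte-identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of all tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "vf_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- NULL
  recordings <- stage("input", {
    if (config$mode == "simulate") {
      ch <- config$cohort
      ch$master_seed <- config$seed
      sim <- generate_cohort(ch, config$process)
      sim$recordings
    } else {
      read_cohort(config$manifest)
    }
  })

  coded <- stage("preprocess+code", prepare_cohort(recordings, window_s = config$window_s))
  steps <- stage("steps", cohort_steps(coded, interval_filter = config$interval_filter,
                                       filter_s = config$filter_s))
  sizes <- stage("sample_sizes", cohort_sample_sizes(lapply(coded, identity)))
  fits <- if (config$fit_params) {
    stage("fits", fit_table(steps, measures = config$measures,
                            min_steps = config$min_steps))
  } else NULL
  summaries <- stage("summaries",
                     summary_feature_table(steps, sizes, measures = config$measures,
                                           fit_params = config$fit_params,
                                           min_steps = config$min_steps))
  correlations <- stage("correlations", correlations_by_recording(steps))

  regressions <- stage("regressions", {
    out <- list()
    for (sp in c("infant", "adult")) {
      res <- tryCatch(lmm_step_vs_interval(steps, sp, "unsplit"),
                      error = function(e) NULL)
      if (!is.null(res)) out[[length(out) + 1L]] <- res
      for (ms in config$measures) {
        dvs <- c("median", "p90")
        if (config$fit_params) {
          pred <- summaries$predominant_family[summaries$speaker_type == sp &
                                                 summaries$measure == ms][1]
          dvs <- c(dvs, switch(pred %||% "none",
                               lognormal = c("meanlog", "sdlog"),
                               pareto = c("xmin", "alpha"),
                               exponential = "rate", NULL))
        }
        for (dv in dvs) {
          res <- tryCatch(
            lmm_summary_features(summaries, dv = dv, speaker_type = sp, measure = ms),
            error = function(e) NULL)
          if (!is.null(res)) out[[length(out) + 1L]] <- res
        }
      }
      res <- tryCatch(glmm_response(coded, sp), error = function(e) NULL)
      if (!is.null(res)) out[[length(out) + 1L]] <- res
      if (config$glmm_steps) {
        res <- tryCatch(glmm_response(coded, sp, include_step_predictors = TRUE),
                        error = function(e) NULL)
        if (!is.null(res)) out[[length(out) + 1L]] <- res
      }
    }
    res <- do.call(rbind, out)
    if (is.null(res)) {
      res <- result_row(character(0), character(0), character(0), numeric(0),
                        numeric(0), integer(0), character(0), logical(0),
                        flag = character(0))
    }
    res
  })

  stage("write", {
    events_all <- do.call(rbind, lapply(names(recordings), function(k) {
      ev <- recordings[[k]]; ev$recording <- k; ev
    }))
    annotated_all <- do.call(rbind, lapply(names(coded), function(k) {
      ev <- coded[[k]]; ev$recording <- k; ev
    }))
    utils::write.csv(events_all, file.path(config$out_dir, "events.csv"), row.names = FALSE)
    utils::write.csv(annotated_all, file.path(config$out_dir, "annotated_events.csv"),
                     row.names = FALSE)
    utils::write.csv(steps, file.path(config$out_dir, "steps.csv"), row.names = FALSE)
    if (!is.null(fits)) {
      utils::write.csv(fits, file.path(config$out_dir, "fits.csv"), row.names = FALSE)
    }
    utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"), row.names = FALSE)
    utils::write.csv(correlations$by_recording,
                     file.path(config$out_dir, "correlations.csv"), row.names = FALSE)
    utils::write.csv(regressions, file.path(config$out_dir, "regressions.csv"),
                     row.names = FALSE)
    if (!is.null(sim)) {
      write_planted_truth(sim$truth, file.path(config$out_dir, "planted_truth.txt"))
    }
    manifest <- list(
      package = "vocalforage",
      version = as.character(utils::packageVersion("vocalforage")),
      seed = config$seed, mode = config$mode,
      window_s = config$window_s, interval_filter = config$interval_filter,
      filter_s = config$filter_s, bins = config$bins,
      measures = config$measures,
      n_recordings = length(recordings))
    jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(recordings = recordings, coded = coded, steps = steps,
                 fits = fits, summaries = summaries,
                 correlations = correlations, regressions = regressions,
                 truth = if (!is.null(sim)) sim$truth else NULL))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
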