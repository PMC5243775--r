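#' Assemble a pipeline configuration
#'
#' A single configuration object drives an end-to-end run: where each data
#' slot comes from (a CSV on disk or a synthetic generator config — exactly
#' one per slot), the decision thresholds, the swim-model coefficients, the
#' statistical options, and the seed. Scalars passed directly to
#' [run_pipeline()] override the config.
#'
#' @param cohort Either `list(csv = path)` or
#'   `list(synthetic = <args for [cohort_config()]>)`.
#' @param flow Either `list(csv = path, meta = path)`,
#'   `list(synthetic = <args for [generate_flow_profile()]>)`, or
#'   `"example"` for the shipped worked-example profile.
#' @param thresholds Named overrides for [threshold_set()]; set
#'   `from_cohort = TRUE` to recompute the trait means from the cohort
#'   (invasion-front definition).
#' @param swim Named overrides for [swim_model()].
#' @param stats Statistical options: `n_groups` (Hosmer–Lemeshow),
#'   `predictors` (columns entering the logit; default length + the three
#'   traits).
#' @param seed Integer master seed.
#' @param output_dir Where outputs are written; `NULL` disables writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = list(synthetic = list(n_individuals = 50)),
                            flow = "example",
                            thresholds = list(),
                            swim = list(),
                            stats = list(),
                            seed = 1L,
                            output_dir = NULL) {
  has_csv <- !is.null(cohort$csv)
  has_syn <- !is.null(cohort$synthetic)
  if (has_csv == has_syn) {
    abort_input("`cohort` must specify exactly one of csv or synthetic")
  }
  structure(
    list(cohort = cohort, flow = flow, thresholds = thresholds,
         swim = swim,
         stats = utils::modifyList(
           list(n_groups = 10L,
                predictors = c("tl_cm", "boldness", "asociability", "activity")),
           stats),
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON or YAML
#' @param path Config file; `.json` read with jsonlite, `.yaml`/`.yml` with
#'   the yaml package (if installed).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_input("YAML configs need the `yaml` package")
    }
    yaml::read_yaml(path)
  } else {
    abort_input("config must be .json or .yaml/.yml")
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full passage-risk pipeline
#'
#' Orchestrates: data acquisition (load or simulate), decision-matrix
#' execution, and the statistical layer (logit fit on the decision outcome,
#' Hosmer–Lemeshow on the fitted probabilities, Spearman correlations between
#' success and the predictors, all-subset AIC table, per-trait moment checks).
#' Every stage failure aborts with a stage-named error. Given a seed the run
#' is fully reproducible; timestamps are isolated to a metadata file so the
#' scientific outputs are diffable.
#'
#' @param config A [pipeline_config()] or a path readable by
#'   [read_pipeline_config()].
#' @param output_dir Overrides `config$output_dir`.
#' @return An object of class `ascent_pipeline` with components `cohort`,
#'   `profile`, `thresholds`, `swim`, `traces`, `summary`, `logit`, `gof`,
#'   `correlations`, `subset_table`, `moments`, `n_in`, `n_excluded`.
#' @examples
#' res <- run_pipeline(pipeline_config(
#'   cohort = list(synthetic = list(n_individuals = 40)), seed = 7))
#' res
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- if (!is.null(output_dir)) output_dir else config$output_dir

  cohort <- stage("cohort", {
    if (!is.null(config$cohort$csv)) {
      read_cohort_csv(config$cohort$csv)
    } else {
      args <- config$cohort$synthetic
      if (is.null(args$seed)) args$seed <- substream_seed(config$seed, "pipeline")
      generate_cohort(do.call(cohort_config, args))
    }
  })

  profile <- stage("flow_profile", {
    if (identical(config$flow, "example")) {
      example_flow_profile()
    } else if (!is.null(config$flow$csv)) {
      read_flow_profile_csv(config$flow$csv, config$flow$meta)
    } else if (!is.null(config$flow$synthetic)) {
      args <- config$flow$synthetic
      if (is.null(args$seed)) args$seed <- config$seed
      do.call(generate_flow_profile, args)
    } else {
      abort_input("`flow` must be 'example', a csv spec, or a synthetic spec")
    }
  })

  swim <- stage("swim_model", do.call(swim_model, config$swim))

  thresholds <- stage("thresholds", {
    overrides <- config$thresholds
    from_cohort <- isTRUE(overrides$from_cohort)
    overrides$from_cohort <- NULL
    thr <- do.call(threshold_set, overrides)
    if (from_cohort) thr <- compute_thresholds(cohort, base = thr)
    thr
  })

  traces <- stage("decision_matrix",
                  run_decision_matrix(cohort, profile, swim, thresholds))
  kept <- traces[!traces$excluded, , drop = FALSE]

  predictors <- intersect(config$stats$predictors, names(kept))
  statistics <- stage("statistics", {
    if (nrow(kept) >= 5L && length(unique(kept$overall)) > 0L) {
      design <- as.matrix(kept[, predictors, drop = FALSE])
      fit <- fit_logit(design, kept$overall)
      gof <- if (nrow(kept) >= config$stats$n_groups) {
        hosmer_lemeshow(fit$fitted, kept$overall,
                        n_groups = config$stats$n_groups)
      } else NULL
      corr <- spearman_matrix(kept[, c(predictors, "overall")])
      subtab <- subset_model_table(design, kept$overall)
      trait_cols <- c("boldness", "activity", "asociability")
      moments <- setNames(
        lapply(trait_cols, function(tr) moment_check(kept[[tr]])),
        trait_cols
      )
      list(logit = fit, gof = gof, correlations = corr,
           subset_table = subtab, moments = moments)
    } else {
      list(logit = NULL, gof = NULL, correlations = NULL,
           subset_table = NULL, moments = NULL)
    }
  })

  result <- structure(
    list(cohort = cohort, profile = profile, thresholds = thresholds,
         swim = swim, traces = traces, summary = summary(traces),
         logit = statistics$logit, gof = statistics$gof,
         correlations = statistics$correlations,
         subset_table = statistics$subset_table,
         moments = statistics$moments,
         n_in = nrow(cohort), n_excluded = sum(traces$excluded),
         seed = config$seed),
    class = "ascent_pipeline"
  )

  if (!is.null(out_dir)) {
    stage("write_outputs", write_pipeline_outputs(result, out_dir))
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort_csv(result$cohort, p("cohort.csv"))
  write_decision_traces_csv(result$traces, p("decision_traces.csv"),
                            summary_path = p("summary.json"))
  write_flow_profile_csv(result$profile, p("flow_profile.csv"),
                         meta_path = p("flow_profile_meta.json"))
  if (!is.null(result$logit)) {
    fit <- result$logit
    jsonlite::write_json(
      list(coefficients = as.list(coef(fit)),
           deviance = fit$deviance, aic = fit$aic,
           lr_chi2 = fit$lr_chi2, lr_df = fit$lr_df, lr_p = fit$lr_p,
           pct_correct = fit$pct_correct,
           separation_warning = fit$separation_warning,
           degenerate = fit$degenerate,
           hosmer_lemeshow = if (!is.null(result$gof)) {
             list(chi2 = result$gof$statistic, df = result$gof$df,
                  p = result$gof$p_value)
           } else NULL),
      p("logit_report.json"), auto_unbox = TRUE, digits = NA
    )
    write_correlation_csv(result$correlations, p("correlations.csv"))
    write_subset_table_csv(result$subset_table, p("subset_table.csv"))
  }
  # timestamps live here and only here
  jsonlite::write_json(
    list(created = format(Sys.time(), tz = "UTC"), seed = result$seed,
         n_in = result$n_in, n_excluded = result$n_excluded),
    p("run_metadata.json"), auto_unbox = TRUE
  )
  invisible(out_dir)
}

#' @export
print.ascent_pipeline <- function(x, ...) {
  cat("Barrier ascent risk assessment\n")
  cat(sprintf("  cohort: %d fish in, %d excluded\n", x$n_in, x$n_excluded))
  print(x$summary)
  if (!is.null(x$logit)) {
    cat("\n")
    print(x$logit)
    if (!is.null(x$gof)) print(x$gof)
  }
  invisible(x)
}

#' @export
summary.ascent_pipeline <- function(object, ...) {
  object$summary
}
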