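#' End-to-end pipeline configuration
#'
#' @param input path to a cohort CSV, or `NULL` to simulate from `spec`.
#' @param spec a [cohort_spec()] used when `input` is `NULL`.
#' @param out_dir output directory (created if absent).
#' @param objective selection objective metric.
#' @param gbt_config,tabu_config classifier and search configurations.
#' @param threshold,k_sd preprocessing parameters (see [preprocess()]).
#' @param k,search_k,test_fraction,n_members evaluation parameters (see
#'   [build_comparison_report()]).
#' @param selectors selectors to compare.
#' @param seed single global seed; per-stage seeds are derived from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input = NULL, spec = cohort_spec(), out_dir = tempfile("run"),
                       objective = "accuracy", gbt_config = gbt_config(),
                       tabu_config = tabu_config(), threshold = 0.5, k_sd = 4,
                       k = 10, search_k = 3, test_fraction = 0.25,
                       n_members = 0, selectors = c("ALL", "SFS", "GSFTS"),
                       seed = 1L) {
  structure(list(input = input, spec = spec, out_dir = out_dir,
                 objective = objective, gbt_config = gbt_config,
                 tabu_config = tabu_config, threshold = threshold,
                 k_sd = k_sd, k = k, search_k = search_k,
                 test_fraction = test_fraction, n_members = n_members,
                 selectors = selectors, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from JSON
#'
#' Scalar fields override the [run_config()] defaults; `gbt` and `tabu`
#' sub-objects feed [gbt_config()] and [tabu_config()], `spec` feeds
#' [cohort_spec()].
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("input", "out_dir", "objective", "threshold", "k_sd", "k",
              "search_k", "test_fraction", "n_members", "selectors", "seed"))
    if (!is.null(obj[[f]])) args[[f]] <- obj[[f]]
  if (!is.null(obj$gbt)) args$gbt_config <- do.call(gbt_config, obj$gbt)
  if (!is.null(obj$tabu)) args$tabu_config <- do.call(tabu_config, obj$tabu)
  if (!is.null(obj$spec)) args$spec <- do.call(cohort_spec, obj$spec)
  do.call(run_config, args)
}

#' Run the full outcome-prediction pipeline
#'
#' Simulate-or-load, preprocess, stratified split, feature selection,
#' final model fit on the selected subset, cross-validated and held-out
#' evaluation, and the selector comparison report. Artifacts written to
#' `config$out_dir`: `cohort.csv` (if simulated), `clean.csv`,
#' `preprocess_report.json`, `selection.json`, `model.json`,
#' `report.json`, `log.txt`, `config_echo.json`.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; the comparison report is
#'   attached as attribute `"report"`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "log.txt")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon))
  say <- function(...) writeLines(sprintf(...), logcon)

  stage <- "load"
  out <- tryCatch({
    raw <- if (is.null(config$input)) {
      cohort <- generate_cohort(config$spec, derive_seed(config$seed, "simulate"))
      write_cohort_csv(cohort$table, file.path(config$out_dir, "cohort.csv"))
      write_truth_json(cohort$truth, file.path(config$out_dir, "truth.json"))
      say("simulated cohort %d x %d", nrow(cohort$table$x), ncol(cohort$table$x))
      cohort$table
    } else {
      say("loading %s", config$input)
      read_cohort_csv(config$input)
    }

    stage <- "preprocess"
    pp <- preprocess(raw, threshold = config$threshold, k_sd = config$k_sd)
    write_cohort_csv(pp$table, file.path(config$out_dir, "clean.csv"))
    jsonlite::write_json(
      list(dropped_features = as.list(pp$report$dropped_features),
           dropped_samples = as.list(pp$report$dropped_samples),
           outliers_flagged = pp$report$outliers_flagged,
           imputation_means = as.list(pp$report$imputation_means)),
      file.path(config$out_dir, "preprocess_report.json"),
      auto_unbox = TRUE, digits = NA)
    say("preprocessed: %d x %d, %d outlier cells flagged",
        nrow(pp$table$x), ncol(pp$table$x), pp$report$outliers_flagged)

    stage <- "compare"
    report <- build_comparison_report(
      pp$table, selectors = config$selectors, objective = config$objective,
      gbt_config = config$gbt_config, tabu_config = config$tabu_config,
      k = config$k, search_k = config$search_k,
      test_fraction = config$test_fraction, n_members = config$n_members,
      seed = config$seed)
    write_report_json(report, file.path(config$out_dir, "report.json"))
    for (s in names(report$selections))
      say("selector %s: %d features, %s = %.4f", s,
          sum(report$selections[[s]]$bits), config$objective,
          report$selections[[s]]$score)

    stage <- "final_model"
    sel <- report$selections[[utils::tail(names(report$selections), 1)]]
    jsonlite::write_json(
      list(bits = sel$bits, objective = sel$objective,
           classifier = sel$classifier, score = sel$score),
      file.path(config$out_dir, "selection.json"),
      auto_unbox = TRUE, digits = NA)
    final <- gbt.labeled_table(pp$table[, which(sel$bits == 1L)],
                               config = config$gbt_config)
    write_gbt_json(final, file.path(config$out_dir, "model.json"))
    say("final model: %d trees on %d features",
        length(final$trees), sum(sel$bits))

    cfg_echo <- config
    cfg_echo$spec <- NULL  # feature specs echoed separately below
    jsonlite::write_json(
      list(seed = config$seed, objective = config$objective,
           selectors = config$selectors, k = config$k,
           search_k = config$search_k, test_fraction = config$test_fraction,
           n_members = config$n_members, threshold = config$threshold,
           k_sd = config$k_sd, gbt = unclass(config$gbt_config),
           tabu = unclass(config$tabu_config),
           r_version = as.character(getRversion()),
           package_version = as.character(utils::packageVersion("gsfts"))),
      file.path(config$out_dir, "config_echo.json"),
      auto_unbox = TRUE, digits = NA)
    report
  }, error = function(e) {
    say("FAILED at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  structure(invisible(config$out_dir), report = out)
}
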