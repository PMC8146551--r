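#' Selector-by-classifier comparison report
#'
#' Benchmarks feature selectors (all features, gain-ranked forward search,
#' recursive feature elimination, and the full gain-sequence forward tabu
#' search) against one or more classifiers: stratified k-fold CV on the
#' training partition, held-out-test metrics, improvement rates versus the
#' all-features baseline (computed from the 2-decimal rounded metrics, as
#' printed in comparison tables), and pairwise McNemar matrices on the test
#' predictions.
#'
#' @param table a preprocessed [labeled_table()].
#' @param selectors subset of `c("ALL", "SFS", "RFE", "GSFTS")`.
#' @param classifiers named list of recipe factories
#'   `function(features) -> recipe`; default a single boosted-tree
#'   classifier `GBT`.
#' @param objective selection objective metric.
#' @param gbt_config a [gbt_config()] for ranking, search and the default
#'   classifier.
#' @param tabu_config a [tabu_config()] for the GSFTS selector.
#' @param k CV folds for reporting (default 10).
#' @param search_k CV folds inside the subset evaluator (default 3, for
#'   cost).
#' @param test_fraction held-out fraction (default 0.25).
#' @param n_members EasyEnsemble members inside the classifier recipes
#'   (0 = single model).
#' @param seed integer seed.
#' @return an object of class `comparison_report`: `cv` and `test` metric
#'   grids, `improvement` rates, `mcnemar` matrices, `selections`.
#' @export
build_comparison_report <- function(table,
                                    selectors = c("ALL", "SFS", "RFE", "GSFTS"),
                                    classifiers = NULL,
                                    objective = "accuracy",
                                    gbt_config = gbt_config(),
                                    tabu_config = tabu_config(),
                                    k = 10, search_k = 3,
                                    test_fraction = 0.25,
                                    n_members = 0, seed = 1L) {
  selectors <- match.arg(selectors, c("ALL", "SFS", "RFE", "GSFTS"),
                         several.ok = TRUE)
  if (is.null(classifiers))
    classifiers <- list(GBT = function(features)
      gbt_recipe(gbt_config, n_members = n_members, features = features,
                 seed = derive_seed(seed, "recipe")))
  parts <- split_train_test(table, test_fraction, derive_seed(seed, "split"))
  train <- parts$train; test <- parts$test

  evaluator <- make_evaluator(train, metric = objective, config = gbt_config,
                              k = search_k, n_members = n_members,
                              seed = derive_seed(seed, "evaluator"))
  p <- ncol(train$x)
  selections <- list()
  for (s in selectors) {
    selections[[s]] <- switch(s,
      ALL = encode_solution(rep(1L, p), objective, "gbt",
                            evaluator(rep(1L, p))),
      SFS = gain_sfs(rank_by_gain(train, gbt_config), evaluator),
      RFE = run_rfe(train, evaluator, gbt_config),
      GSFTS = {
        tc <- tabu_config
        tc$seed <- derive_seed(seed, "gsfts")
        gsfts(train, objective = objective, gbt_config = gbt_config,
              tabu_config = tc, evaluator = evaluator)$encoding
      })
  }

  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  cv_grid <- list(); test_grid <- list(); test_preds <- list()
  for (s in selectors) for (cl in names(classifiers)) {
    key <- paste(s, cl, sep = ".")
    recipe <- classifiers[[cl]](selections[[s]]$bits)
    cv_grid[[key]] <- kfold_cv(train, recipe, k = k,
                               seed = derive_seed(seed, "cv"))
    fit <- recipe(train)
    pr <- predict(fit, test$x, type = "prob")
    test_grid[[key]] <- compute_metrics(test$y, as.integer(pr >= 0.5), pr)
    test_preds[[key]] <- as.integer(pr >= 0.5)
  }

  # improvement rates vs the ALL baseline, from rounded printed values
  improvement <- list()
  if ("ALL" %in% selectors) {
    for (s in selectors) for (cl in names(classifiers)) {
      key <- paste(s, cl, sep = ".")
      base_key <- paste("ALL", cl, sep = ".")
      improvement[[key]] <- stats::setNames(vapply(metric_names, function(m) {
        b <- round_half_up(cv_grid[[base_key]]$mean[m], 2)
        v <- round_half_up(cv_grid[[key]]$mean[m], 2)
        if (b > 0) improvement_rate(b, v) else NA_real_
      }, numeric(1)), metric_names)
    }
  }

  mcnemar_selectors <- list()
  for (cl in names(classifiers)) {
    mat_s <- matrix(NA_real_, length(selectors), length(selectors),
                    dimnames = list(selectors, selectors))
    mat_p <- mat_s
    for (a in selectors) for (b in selectors) if (a != b) {
      mc <- mcnemar_from_predictions(test$y,
                                     test_preds[[paste(a, cl, sep = ".")]],
                                     test_preds[[paste(b, cl, sep = ".")]])
      mat_s[a, b] <- mc$statistic
      mat_p[a, b] <- mc$p_value
    }
    mcnemar_selectors[[cl]] <- list(statistic = mat_s, p_value = mat_p)
  }

  structure(list(selections = selections, cv = cv_grid, test = test_grid,
                 improvement = improvement, mcnemar = mcnemar_selectors,
                 selectors = selectors, classifiers = names(classifiers),
                 objective = objective, k = k, seed = seed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  cat(sprintf("Comparison report (%d-fold CV mean +/- sd; objective %s)\n",
              x$k, x$objective))
  for (cl in x$classifiers) {
    cat(sprintf("\nClassifier %s:\n", cl))
    hdr <- sprintf("  %-8s %s", "subset",
                   paste(sprintf("%-14s", metric_names), collapse = ""))
    cat(hdr, "\n")
    for (s in x$selectors) {
      key <- paste(s, cl, sep = ".")
      cells <- vapply(metric_names, function(m)
        sprintf("%.2f +/- %.2f", round_half_up(x$cv[[key]]$mean[m], 2),
                round_half_up(x$cv[[key]]$sd[m], 2)), character(1))
      cat(sprintf("  %-8s %s\n", s, paste(sprintf("%-14s", cells),
                                          collapse = "")))
      if (length(x$improvement) && s != "ALL") {
        rates <- vapply(metric_names, function(m)
          sprintf("(%.1f%%)", x$improvement[[key]][m]), character(1))
        cat(sprintf("  %-8s %s\n", "", paste(sprintf("%-14s", rates),
                                             collapse = "")))
      }
    }
    cat("  McNemar statistics on test predictions ('/' = self):\n")
    mat <- x$mcnemar[[cl]]$statistic
    for (a in rownames(mat)) {
      cells <- vapply(colnames(mat), function(b)
        if (a == b) "/" else sprintf("%.3f", mat[a, b]), character(1))
      cat(sprintf("    %-8s %s\n", a, paste(sprintf("%-8s", cells),
                                            collapse = "")))
    }
  }
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' Cells are keyed `selector.classifier.metric`.
#'
#' @param report a [build_comparison_report()] result.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  cells <- list()
  for (key in names(report$cv)) {
    for (m in metric_names) {
      cells[[paste(key, m, sep = ".")]] <- list(
        cv_mean = unname(report$cv[[key]]$mean[m]),
        cv_sd = unname(report$cv[[key]]$sd[m]),
        test = report$test[[key]][[m]],
        improvement = if (length(report$improvement))
          unname(report$improvement[[key]][m]) else NULL)
    }
  }
  obj <- list(objective = report$objective, k = report$k, seed = report$seed,
              cells = cells,
              selections = lapply(report$selections, function(e)
                list(bits = e$bits, objective = e$objective,
                     classifier = e$classifier, score = e$score)),
              mcnemar = report$mcnemar)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
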