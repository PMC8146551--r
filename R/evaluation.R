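#' Binary classification metrics
#'
#' Accuracy, precision, recall, F1 and AUC. AUC uses the rank statistic
#' with midranks for ties (the Mann-Whitney form); zero-denominator
#' precision / recall / F1 are reported as 0 with a warning flag in the
#' `"degenerate"` attribute.
#'
#' @param labels true 0/1 labels (both classes must be present).
#' @param predicted 0/1 predicted classes.
#' @param scores continuous scores for AUC (e.g. predicted probabilities).
#' @return a named list of class `metric_set` with `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`.
#' @export
compute_metrics <- function(labels, predicted, scores) {
  stopifnot(length(labels) == length(predicted),
            length(labels) == length(scores))
  if (length(unique(labels)) < 2)
    stop("AUC undefined: labels contain a single class")
  tp <- sum(labels == 1 & predicted == 1)
  fp <- sum(labels == 0 & predicted == 1)
  fn <- sum(labels == 1 & predicted == 0)
  tn <- sum(labels == 0 & predicted == 0)
  degenerate <- character(0)
  precision <- if (tp + fp == 0) { degenerate <- c(degenerate, "precision"); 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { degenerate <- c(degenerate, "recall"); 0 } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) { degenerate <- c(degenerate, "f1"); 0 } else
    2 * precision * recall / (precision + recall)
  r <- rank(scores)  # midranks for ties
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1, auc = auc),
            degenerate = degenerate, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f  auc %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

#' Stratified fold assignment
#'
#' @param y 0/1 labels.
#' @param k number of folds; every class must have at least `k` members.
#' @param seed integer seed.
#' @return an integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k, seed) {
  if (any(table(y) < k)) stop("every class needs >= k members for stratification")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Model recipe for cross-validation
#'
#' A recipe is a function `f(train_table)` returning a fitted object that
#' `predict(object, x, type = "prob")` accepts. This builder wraps the
#' boosted-tree classifier (optionally as an EasyEnsemble), restricted to
#' a feature subset, with min-max scaling fitted inside the training fold
#' and applied to held-out rows.
#'
#' @param config a [gbt_config()].
#' @param n_members EasyEnsemble members; 0 fits a single model.
#' @param features optional integer indices (or 0/1 bits) of the feature
#'   subset to use.
#' @param scale fit min-max scaling on the training fold (default TRUE).
#' @param seed seed for the ensemble draws.
#' @return a recipe function.
#' @export
gbt_recipe <- function(config = gbt_config(), n_members = 0, features = NULL,
                       scale = TRUE, seed = 1L) {
  cols <- NULL
  if (!is.null(features)) {
    cols <- if (all(features %in% c(0, 1)) && length(features) > 1)
      which(as.integer(features) == 1L) else as.integer(features)
  }
  function(train) {
    use <- if (is.null(cols)) seq_len(ncol(train$x)) else cols
    sub <- train[, use]
    params <- NULL
    if (scale) {
      sc <- minmax_scale(sub)
      sub <- sc$table
      params <- sc$report$scale_params
    }
    model <- if (n_members > 0)
      fit_easy_ensemble(sub, config = config, n_members = n_members,
                        seed = seed)
    else gbt.labeled_table(sub, config = config)
    structure(list(model = model, cols = use, scale_params = params),
              class = "gbt_recipe_fit")
  }
}

#' @export
predict.gbt_recipe_fit <- function(object, newdata, type = "prob", ...) {
  if (inherits(newdata, "labeled_table")) newdata <- newdata$x
  x <- as.matrix(newdata)[, object$cols, drop = FALSE]
  if (!is.null(object$scale_params)) {
    rng <- object$scale_params$max - object$scale_params$min
    rng[rng == 0] <- 1
    x <- sweep(sweep(x, 2, object$scale_params$min), 2, rng, "/")
  }
  predict(object$model, x, type = type)
}

#' Stratified k-fold cross-validation
#'
#' Fits the recipe on each training fold (any preprocessing the recipe
#' performs — scaling, ensemble draws — happens inside the fold) and
#' evaluates on the held-out fold.
#'
#' @param table a [labeled_table()].
#' @param recipe a recipe function, e.g. from [gbt_recipe()].
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return an object of class `cv_result`: `folds` (list of
#'   [compute_metrics()] sets), `mean` and `sd` per metric, `k`, `seed`.
#' @export
kfold_cv <- function(table, recipe, k = 10, seed = 1L) {
  folds <- make_folds(table$y, k, seed)
  per_fold <- lapply(seq_len(k), function(fold) {
    tr <- table[folds != fold, ]
    te <- table[folds == fold, ]
    fit <- recipe(tr)
    pr <- predict(fit, te$x, type = "prob")
    compute_metrics(te$y, as.integer(pr >= 0.5), pr)
  })
  m <- sapply(per_fold, unlist)  # metrics x folds
  structure(list(folds = per_fold, mean = rowMeans(m),
                 sd = apply(m, 1, stats::sd), k = k, seed = seed,
                 fold_id = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold stratified CV (reported mean +/- sd):\n", x$k))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.2f +/- %.2f\n", m, round_half_up(x$mean[m], 2),
                round_half_up(x$sd[m], 2)))
  invisible(x)
}

#' Improvement rate versus a baseline
#'
#' `100 * (value - baseline) / baseline`, rounded half-up to one decimal —
#' the "increase rate" convention of comparison tables (inputs are the
#' printed, 2-decimal metric values).
#'
#' @param baseline baseline metric (> 0).
#' @param value improved metric.
#' @return the percent improvement, one decimal.
#' @examples
#' improvement_rate(0.89, 0.96)  # 7.9
#' @export
improvement_rate <- function(baseline, value) {
  if (baseline <= 0) stop("baseline must be > 0")
  round_half_up(100 * (value - baseline) / baseline, 1)
}

#' Upper tail of the chi-square distribution with 1 df
#'
#' `P(X > x) = erfc(sqrt(x / 2))`, evaluated through the normal tail
#' identity `erfc(z) = 2 pnorm(-z sqrt(2))`.
#'
#' @param x nonnegative statistic value.
#' @return the upper-tail probability.
#' @examples
#' chi2_sf_1df(3.8415)  # ~0.05, the alpha = 0.05 critical value
#' @export
chi2_sf_1df <- function(x) {
  stopifnot(all(x >= 0))
  2 * stats::pnorm(-sqrt(x))
}

#' McNemar paired comparison of two classifiers
#'
#' From the discordant counts `b` (A correct, B wrong) and `c` (A wrong,
#' B correct), the continuity-corrected statistic
#' `(|b - c| - 1)^2 / (b + c)` referred to chi-square with 1 df. When
#' `b + c = 0` the statistic is 0 and p = 1.
#'
#' @param labels true labels.
#' @param predsA,predsB the two classifiers' predicted classes.
#' @return a list of class `mcnemar_result` with `b`, `c`, `statistic`,
#'   `p_value`.
#' @export
mcnemar_from_predictions <- function(labels, predsA, predsB) {
  stopifnot(length(labels) == length(predsA),
            length(labels) == length(predsB))
  okA <- predsA == labels
  okB <- predsB == labels
  b <- sum(okA & !okB)
  c_ <- sum(!okA & okB)
  stat <- if (b + c_ > 0) (abs(b - c_) - 1)^2 / (b + c_) else 0
  structure(list(b = b, c = c_, statistic = stat,
                 p_value = if (b + c_ > 0) chi2_sf_1df(stat) else 1),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar: b=%d c=%d statistic=%.3f p=%.3f\n",
              x$b, x$c, x$statistic, x$p_value))
  invisible(x)
}

#' Exhaustive grid search with cross-validation
#'
#' Evaluates every point of the Cartesian grid of classifier
#' hyperparameters by stratified k-fold CV on the chosen objective (the
#' tuning index of the motivating study is F1) and returns the argmax
#' (ties resolved to the first point in grid order) plus the full score
#' surface.
#'
#' @param grid named list of parameter value vectors ([gbt_config()]
#'   arguments, e.g. `list(max_depth = c(3, 7), n_estimators = c(20, 70))`).
#' @param table a [labeled_table()].
#' @param objective metric to maximize (default `"f1"`).
#' @param k CV folds.
#' @param seed integer seed.
#' @param n_members EasyEnsemble members per fit (0 = single model).
#' @return a list with `best` (named parameter list), `best_score`, and
#'   `surface` (a `data.frame`: grid columns + `score`).
#' @export
grid_search <- function(grid, table, objective = "f1", k = 5, seed = 1L,
                        n_members = 0) {
  stopifnot(length(grid) >= 1, all(lengths(grid) >= 1))
  surface <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  scores <- vapply(seq_len(nrow(surface)), function(i) {
    cfg <- do.call(gbt_config, as.list(surface[i, , drop = FALSE]))
    cv <- kfold_cv(table, gbt_recipe(cfg, n_members = n_members, seed = seed),
                   k = k, seed = seed)
    unname(cv$mean[objective])
  }, numeric(1))
  surface$score <- scores
  best_i <- which.max(scores)  # first maximum in grid order
  list(best = as.list(surface[best_i, setdiff(names(surface), "score"),
                              drop = FALSE]),
       best_score = scores[best_i], surface = surface)
}
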