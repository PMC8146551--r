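#' Drop features and samples with too many missing values
#'
#' Features whose missing fraction strictly exceeds `threshold` are removed
#' first; then samples whose missing fraction over the retained features
#' strictly exceeds `threshold` are removed.
#'
#' @param table a [labeled_table()].
#' @param threshold missing-fraction cutoff in (0, 1); default 0.5.
#' @return a list with the reduced `table` and a `report` listing
#'   `dropped_features` and `dropped_samples` with their missing fractions.
#' @export
drop_high_missing <- function(table, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  x <- table$x
  ffrac <- colMeans(is.na(x))
  drop_f <- ffrac > threshold
  if (all(drop_f)) stop("all features exceed the missing threshold")
  x2 <- x[, !drop_f, drop = FALSE]
  sfrac <- rowMeans(is.na(x2))
  drop_s <- sfrac > threshold
  if (all(drop_s)) stop("all samples exceed the missing threshold")
  out <- labeled_table(x2[!drop_s, , drop = FALSE], table$y[!drop_s],
                       sample_ids = rownames(x2)[!drop_s])
  list(table = out,
       report = list(dropped_features = ffrac[drop_f],
                     dropped_samples = sfrac[drop_s]))
}

#' Mean-impute missing cells
#'
#' Each missing cell is replaced by the mean of its feature's observed
#' values.
#'
#' @param table a [labeled_table()].
#' @return a list with the imputed `table` and a `report` holding the
#'   per-feature `imputation_means`.
#' @export
impute_mean <- function(table) {
  x <- table$x
  if (any(colSums(!is.na(x)) == 0))
    stop("all-missing feature: drop it before imputing")
  mu <- colMeans(x, na.rm = TRUE)
  na <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na) > 0) x[na] <- mu[na[, 2]]
  list(table = labeled_table(x, table$y, rownames(x)),
       report = list(imputation_means = mu))
}

#' Flag and re-impute gross outliers
#'
#' Cells more than `k_sd` standard deviations from their feature mean are
#' set missing and replaced by the mean of the remaining values. By default
#' the flag-impute cycle repeats until no cell exceeds the bound (a fixed
#' point), which makes the full preprocessing pipeline idempotent; set
#' `max_pass = 1` for a single sweep. Constant features (sd = 0) are never
#' flagged. Alternatively `action = "drop_sample"` deletes the offending
#' rows outright.
#'
#' @param table a [labeled_table()] with no missing cells.
#' @param k_sd z-score cutoff (default 4).
#' @param action `"impute"` (cell-level, default) or `"drop_sample"`.
#' @param max_pass maximum flag-impute sweeps (default `Inf` = to fixpoint).
#' @return a list with the cleaned `table` and a `report` containing
#'   `outliers_flagged` (count) and `outlier_cells` (sample, feature,
#'   replacement value) for exact replay.
#' @export
remove_outliers <- function(table, k_sd = 4, action = c("impute", "drop_sample"),
                            max_pass = Inf) {
  action <- match.arg(action)
  x <- table$x
  if (anyNA(x)) stop("impute missing cells before outlier removal")
  cells <- data.frame(sample_id = character(0), feature = character(0),
                      replacement = numeric(0), stringsAsFactors = FALSE)
  if (is.finite(k_sd)) {
    if (action == "drop_sample") {
      mu <- colMeans(x); s <- apply(x, 2, stats::sd)
      bad <- abs(sweep(sweep(x, 2, mu), 2, ifelse(s == 0, Inf, s), "/")) > k_sd
      keep <- rowSums(bad) == 0
      out <- labeled_table(x[keep, , drop = FALSE], table$y[keep],
                           rownames(x)[keep])
      return(list(table = out,
                  report = list(outliers_flagged = sum(!keep),
                                outlier_cells = cells)))
    }
    pass <- 0
    repeat {
      pass <- pass + 1
      mu <- colMeans(x); s <- apply(x, 2, stats::sd)
      z <- abs(sweep(sweep(x, 2, mu), 2, ifelse(s == 0, Inf, s), "/"))
      bad <- which(z > k_sd, arr.ind = TRUE)
      if (nrow(bad) == 0 || pass > max_pass) break
      x[bad] <- NA_real_
      mu2 <- colMeans(x, na.rm = TRUE)
      repl <- mu2[bad[, 2]]
      x[bad] <- repl
      cells <- rbind(cells, data.frame(
        sample_id = rownames(x)[bad[, 1]],
        feature = colnames(x)[bad[, 2]],
        replacement = repl, stringsAsFactors = FALSE))
      if (pass >= max_pass) break
    }
  }
  list(table = labeled_table(x, table$y, rownames(x)),
       report = list(outliers_flagged = nrow(cells), outlier_cells = cells))
}

#' Min-max scale features to the unit interval
#'
#' Maps each feature through `(x - min) / (max - min)`. Constant features
#' map to 0. The fitted `(min, max)` pairs are returned so a held-out
#' partition can be transformed with training-set parameters (values
#' outside the training range extrapolate beyond \[0, 1\]; no clipping).
#'
#' @param table a [labeled_table()] with no missing cells.
#' @param params optional previously fitted scale parameters (a list with
#'   `min` and `max` vectors); when supplied they are applied as-is.
#' @return a list with the scaled `table` and a `report` holding
#'   `scale_params`.
#' @export
minmax_scale <- function(table, params = NULL) {
  x <- table$x
  if (anyNA(x)) stop("impute missing cells before scaling")
  if (is.null(params)) {
    params <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  }
  rng <- params$max - params$min
  rng[rng == 0] <- 1  # constant feature -> 0 after centering
  x <- sweep(sweep(x, 2, params$min), 2, rng, "/")
  list(table = labeled_table(x, table$y, rownames(x)),
       report = list(scale_params = params))
}

#' Run the full preprocessing pipeline
#'
#' Missing-value dropping, mean imputation, outlier removal, and min-max
#' scaling, in that order.
#'
#' @inheritParams drop_high_missing
#' @inheritParams remove_outliers
#' @return a list with the processed `table` and the combined
#'   `report` (class `preprocess_report`).
#' @seealso [apply_preprocess()] to replay a report on raw data.
#' @export
preprocess <- function(table, threshold = 0.5, k_sd = 4,
                       action = c("impute", "drop_sample")) {
  s1 <- drop_high_missing(table, threshold)
  s2 <- impute_mean(s1$table)
  s3 <- remove_outliers(s2$table, k_sd, action = action)
  s4 <- minmax_scale(s3$table)
  report <- structure(c(s1$report, s2$report, s3$report, s4$report),
                      class = "preprocess_report")
  list(table = s4$table, report = report)
}

#' Replay a preprocessing report on the raw table
#'
#' Applies the recorded drops, imputation means, outlier replacements and
#' scale parameters; reproduces the processed table exactly.
#'
#' @param report a `preprocess_report` from [preprocess()].
#' @param table the raw [labeled_table()] the report was fitted on (or a
#'   new table with the same features, e.g. a held-out partition).
#' @return the transformed [labeled_table()].
#' @export
apply_preprocess <- function(report, table) {
  keep_f <- setdiff(colnames(table$x), names(report$dropped_features))
  keep_s <- setdiff(rownames(table$x), names(report$dropped_samples))
  x <- table$x[keep_s, keep_f, drop = FALSE]
  y <- table$y[match(keep_s, rownames(table$x))]
  mu <- report$imputation_means[colnames(x)]
  na <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na) > 0) x[na] <- mu[na[, 2]]
  oc <- report$outlier_cells
  oc <- oc[oc$sample_id %in% rownames(x), , drop = FALSE]
  if (nrow(oc) > 0)
    x[cbind(match(oc$sample_id, rownames(x)), match(oc$feature, colnames(x)))] <-
      oc$replacement
  minmax_scale(labeled_table(x, y, rownames(x)),
               params = report$scale_params)$table
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report> %d features dropped, %d samples dropped, %d outlier cells flagged, %d features scaled\n",
              length(x$dropped_features), length(x$dropped_samples),
              x$outliers_flagged, length(x$scale_params$min)))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits a labeled table into train and test partitions, stratifying on
#' the label so the test positive rate is within one count of the overall
#' rate. The study design reserves 25% as a held-out test set.
#'
#' @param table a [labeled_table()].
#' @param test_fraction fraction held out (default 0.25).
#' @param seed integer seed.
#' @return a list with `train` and `test` labeled tables.
#' @export
split_train_test <- function(table, test_fraction = 0.25, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (length(unique(table$y)) < 2) stop("both classes must be present")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- which(table$y == cl)
    n_test <- round(length(idx) * test_fraction)
    if (n_test < 1 || n_test >= length(idx))
      stop("a partition would lack a class; adjust test_fraction")
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  list(train = table[-test_idx, ], test = table[test_idx, ])
}
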