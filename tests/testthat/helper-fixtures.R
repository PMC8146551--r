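# Shared fixtures: small configs and cohorts that keep the suite fast.

quick_gbt <- function(n_estimators = 10, max_depth = 2, ...) {
  gbt_config(n_estimators = n_estimators, max_depth = max_depth, ...)
}

# clean (no missing/outlier cells) small cohort, optionally preprocessed;
# at tiny n the minority fraction rises to keep >= 12 positives
small_cohort <- function(n = 200, p = 12, seed = 1, n_informative = NULL,
                         preprocessed = FALSE) {
  spec <- cohort_spec(n, p, missing_rate = 0, outlier_rate = 0,
                      minority_fraction = min(0.4, max(0.125, 12 / n)),
                      n_informative = n_informative)
  tab <- generate_cohort(spec, seed = seed)$table
  if (preprocessed) tab <- preprocess(tab)$table
  tab
}

# rank AUC of a score vector against 0/1 labels (independent of the
# package's compute_metrics; used as a tiny oracle helper)
rank_auc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# a fake importance ranking over n features in the given index order
fake_ranking <- function(order_idx) {
  data.frame(feature = paste0("V", order_idx), index = order_idx,
             split_count = rev(seq_along(order_idx)),
             total_gain = rev(seq_along(order_idx)),
             average_gain = rev(seq_along(order_idx)))
}

# evaluator returning planted scores keyed by the set of selected indices;
# `default` covers unplanted subsets
planted_evaluator <- function(scores, default = 0, metric = "accuracy") {
  f <- function(bits) {
    key <- paste(which(bits == 1L), collapse = ",")
    if (!is.null(scores[[key]])) scores[[key]] else default
  }
  attr(f, "metric") <- metric
  attr(f, "classifier") <- "planted"
  f
}
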