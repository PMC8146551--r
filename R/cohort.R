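#' Feature specification for the synthetic cohort generator
#'
#' @param name feature name.
#' @param kind `"continuous"` (truncated normal) or `"binary"` (Bernoulli
#'   with success probability `mean`).
#' @param mean,sd population mean and standard deviation (`sd` ignored for
#'   binary features).
#' @param low,high truncation bounds for continuous features.
#' @param informative does the feature contribute to the outcome?
#' @param effect_weight log-odds contribution per standardized unit; must be
#'   nonzero exactly when `informative`.
#' @return a one-row `data.frame` (rows of several specs can be bound).
#' @export
feature_spec <- function(name, kind = c("continuous", "binary"),
                         mean, sd = NA_real_, low = -Inf, high = Inf,
                         informative = FALSE, effect_weight = 0) {
  kind <- match.arg(kind)
  if (kind == "continuous" && (is.na(sd) || sd <= 0))
    stop("continuous features need sd > 0")
  if (low >= high) stop("low must be < high")
  if (informative != (effect_weight != 0))
    stop("effect_weight must be nonzero iff informative")
  data.frame(name = name, kind = kind, mean = mean, sd = sd,
             low = low, high = high, informative = informative,
             effect_weight = effect_weight, stringsAsFactors = FALSE)
}

# The clinical indicators with published summary statistics: name,
# mean, sd, range. Sex is a binary indicator (prevalence 0.5 assumed).
table1_features <- function() {
  rbind(
    feature_spec("Sex", "binary", mean = 0.5, low = 0, high = 1),
    feature_spec("AGE", mean = 38.31, sd = 11.42, low = 15, high = 76,
                 informative = TRUE, effect_weight = 0.4),
    feature_spec("BMI", mean = 27.35, sd = 4.19, low = 16.32, high = 50.93,
                 informative = TRUE, effect_weight = -0.489),
    feature_spec("HR", mean = 76.28, sd = 12.71, low = 49, high = 121),
    feature_spec("RYDBPL", mean = 98.53, sd = 16.8, low = 57, high = 160),
    feature_spec("EF", mean = 64.34, sd = 5.81, low = 30, high = 77),
    feature_spec("NEUT", mean = 60.77, sd = 7.89, low = 36.1, high = 82.6),
    feature_spec("FT4", mean = 1.17, sd = 0.188, low = 0.32, high = 1.91),
    feature_spec("MAUCR", mean = 59.56, sd = 133.67, low = 0, high = 1081.26),
    feature_spec("ESR", mean = 7.21, sd = 6.89, low = 1, high = 44),
    feature_spec("ET", mean = 0.32, sd = 0.76, low = 0.1, high = 8.47),
    feature_spec("RARMSBP", mean = 149.05, sd = 20.91, low = 100, high = 233,
                 informative = TRUE, effect_weight = 0.578),
    feature_spec("BAPWVR", mean = 15.65, sd = 3.05, low = 7.3, high = 28.6,
                 informative = TRUE, effect_weight = -0.667),
    feature_spec("HIGHSBP", mean = 166.17, sd = 20.13, low = 152.25, high = 242,
                 informative = TRUE, effect_weight = 0.756)
  )
}

#' Default synthetic cohort specification
#'
#' Emulates the scale and structure of the hypertension-outcome study
#' cohort: 752 patients, 84 preprocessed indicators with a 1:7
#' positive:negative imbalance. The first 14 features carry the published
#' summary statistics (e.g. AGE mean 38.31, sd 11.42, range 15-76); the
#' remainder are generic continuous indicators. Ten features are
#' informative, with alternating-sign log-odds weights of magnitude 0.4 to
#' 1.2 (the selected subsets in the study contained 9-16 features).
#'
#' @param n_samples,n_features cohort dimensions.
#' @param minority_fraction target positive prevalence (1:7 imbalance =
#'   1/8).
#' @param missing_rate,outlier_rate fraction of feature cells set missing /
#'   replaced by gross outliers (> 6 sd), to exercise preprocessing.
#' @param n_informative optional override: mark exactly this many
#'   continuous features informative (evenly spaced through the index
#'   range, alternating-sign weights of magnitude 0.4 to 1.2) instead of
#'   the default set of 10.
#' @return a list of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_samples = 752, n_features = 84,
                        minority_fraction = 0.125,
                        missing_rate = 0.05, outlier_rate = 0.01,
                        n_informative = NULL) {
  feats <- table1_features()
  if (n_features < nrow(feats))
    feats <- feats[seq_len(n_features), , drop = FALSE]
  # informative generic features, spread through the index range
  n_extra <- n_features - nrow(feats)
  extra_inf <- if (n_extra > 0) c(20L, 30L, 40L, 50L, 60L) else integer(0)
  extra_inf <- extra_inf[extra_inf <= n_features]
  n_inf_so_far <- sum(feats$informative)
  # alternating-sign magnitudes 0.4..1.2 across the full informative set
  mags <- seq(0.4, 1.2, length.out = max(n_inf_so_far + length(extra_inf), 1))
  signs <- rep_len(c(1, -1), length(mags))
  w_extra <- (mags * signs)[seq_len(length(extra_inf)) + n_inf_so_far]
  if (n_extra > 0) {
    extras <- do.call(rbind, lapply(seq_len(n_extra), function(k) {
      idx <- nrow(feats) + k
      inf <- idx %in% extra_inf
      feature_spec(paste0("GEN", idx), mean = 50, sd = 10, low = 10, high = 90,
                   informative = inf,
                   effect_weight = if (inf) w_extra[match(idx, extra_inf)] else 0)
    }))
    feats <- rbind(feats, extras)
  }
  if (!is.null(n_informative)) {
    cont <- which(feats$kind == "continuous")
    if (n_informative < 1 || n_informative > length(cont))
      stop("n_informative out of range")
    feats$informative <- FALSE
    feats$effect_weight <- 0
    idx <- cont[unique(round(seq(1, length(cont),
                                 length.out = n_informative)))]
    mags <- seq(0.4, 1.2, length.out = length(idx))
    feats$informative[idx] <- TRUE
    feats$effect_weight[idx] <- mags * rep_len(c(1, -1), length(idx))
  }
  if (sum(feats$informative) < 1)
    stop("at least one informative feature is required")
  structure(list(n_samples = n_samples, n_features = n_features,
                 minority_fraction = minority_fraction,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 features = feats),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d x %d, prevalence %.3f, %d informative, missing %.2f, outlier %.3f\n",
              x$n_samples, x$n_features, x$minority_fraction,
              sum(x$features$informative), x$missing_rate, x$outlier_rate))
  invisible(x)
}

# inverse-CDF draw from N(mean, sd) truncated to [low, high]
rtruncnorm <- function(n, mean, sd, low, high) {
  a <- stats::pnorm((low - mean) / sd)
  b <- stats::pnorm((high - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, a, b))
}

#' Generate a synthetic labeled cohort
#'
#' Draws each feature independently (truncated normal for continuous,
#' Bernoulli for binary), then draws the outcome label from a logistic
#' model that is linear in the z-scored informative features. The
#' intercept is solved by bisection so the expected prevalence equals
#' `minority_fraction`. Afterwards `missing_rate` of the feature cells are
#' blanked and `outlier_rate` of the continuous feature cells are replaced
#' by values 6-10 sd from the feature mean; the label column is never
#' touched.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; identical `(spec, seed)` gives identical
#'   output.
#' @return a list with `table` (a [labeled_table()]) and `truth`, the
#'   planted ground truth (`informative_indices`, `effect_weights`,
#'   `latent_intercept`, `seed`).
#' @examples
#' spec <- cohort_spec(n_samples = 120, n_features = 10)
#' cohort <- generate_cohort(spec, seed = 1)
#' mean(cohort$table$y)
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$minority_fraction * spec$n_samples < 10)
    stop("minority_fraction * n_samples < 10: too few positives for stratified CV")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- spec$n_samples
  fs <- spec$features
  x <- matrix(NA_real_, n, nrow(fs), dimnames = list(
    paste0("s", seq_len(n)), fs$name))
  for (j in seq_len(nrow(fs))) {
    x[, j] <- if (fs$kind[j] == "binary")
      stats::rbinom(n, 1, fs$mean[j])
    else
      rtruncnorm(n, fs$mean[j], fs$sd[j], fs$low[j], fs$high[j])
  }

  inf <- which(fs$informative)
  z <- scale(x[, inf, drop = FALSE])
  z[is.nan(z)] <- 0
  eta <- drop(z %*% fs$effect_weight[inf])
  # bisection for the intercept: mean prevalence is monotone in it
  f <- function(b) mean(sigmoid(b + eta)) - spec$minority_fraction
  lo <- -30; hi <- 30
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  intercept <- (lo + hi) / 2
  y <- stats::rbinom(n, 1, sigmoid(intercept + eta))
  # guard the degenerate draw (absent classes break every downstream step)
  if (sum(y) == 0) y[which.max(eta)] <- 1L
  if (sum(y) == n) y[which.min(eta)] <- 0L

  # gross outliers first (into continuous cells), then missingness
  cont <- which(fs$kind == "continuous")
  if (spec$outlier_rate > 0 && length(cont) > 0) {
    cells <- which(matrix(TRUE, n, length(cont)))
    k <- round(spec$outlier_rate * length(cells))
    if (k > 0) {
      pick <- sample(cells, k)
      rows <- (pick - 1) %% n + 1
      cols <- cont[(pick - 1) %/% n + 1]
      mult <- 6 + stats::runif(k, 0, 4)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      x[cbind(rows, cols)] <- fs$mean[cols] + sgn * mult * fs$sd[cols]
    }
  }
  if (spec$missing_rate > 0) {
    k <- round(spec$missing_rate * length(x))
    if (k > 0) x[sample(length(x), k)] <- NA_real_
  }

  list(table = labeled_table(x, y),
       truth = list(informative_indices = inf,
                    effect_weights = fs$effect_weight,
                    latent_intercept = intercept,
                    seed = seed))
}

#' Tiny deterministic fixture for hand-checkable tree tests
#'
#' A 12-row, 4-feature table in which feature `SEP` perfectly separates
#' the two classes (label 1 iff `SEP` > 0.5); the other three features are
#' uninformative by construction.
#'
#' @return a [labeled_table()].
#' @export
worked_fixture <- function() {
  sep <- c(0.05, 0.15, 0.2, 0.3, 0.4, 0.45, 0.55, 0.6, 0.7, 0.8, 0.9, 0.95)
  x <- cbind(
    SEP = sep,
    CONST = rep(2, 12),
    ALT = rep(c(0, 1), 6),
    NOISE = c(0.3, 0.9, 0.1, 0.7, 0.5, 0.2, 0.8, 0.4, 0.6, 0.05, 0.95, 0.35))
  labeled_table(x, as.integer(sep > 0.5))
}

#' Write planted ground truth as JSON
#'
#' @param truth the `truth` element of [generate_cohort()] output.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
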