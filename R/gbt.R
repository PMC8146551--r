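#' Boosted-tree configuration
#'
#' Hyperparameters of the second-order boosted-tree classifier. The tuned
#' values from the motivating study are max depth 7 with 70 trees;
#' regularization and learning-rate defaults are the conventional ones
#' (the study does not report them).
#'
#' @param n_estimators number of boosting rounds (>= 1).
#' @param max_depth maximum tree depth (>= 1).
#' @param learning_rate shrinkage eta in (0, 1].
#' @param reg_lambda L2 leaf-weight regularization lambda (>= 0).
#' @param gamma per-leaf complexity penalty; a split must gain more than
#'   gamma to be kept.
#' @param base_score initial predicted probability (margin =
#'   `qlogis(base_score)`).
#' @param seed integer seed (the exact greedy fit itself is deterministic;
#'   the seed feeds ensemble subsampling).
#' @return a list of class `gbt_config`.
#' @export
gbt_config <- function(n_estimators = 70, max_depth = 7, learning_rate = 0.3,
                       reg_lambda = 1.0, gamma = 0.0, base_score = 0.5,
                       seed = 1L) {
  stopifnot(n_estimators >= 1, max_depth >= 1,
            learning_rate > 0, learning_rate <= 1,
            reg_lambda >= 0, gamma >= 0,
            base_score > 0, base_score < 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, reg_lambda = reg_lambda,
                 gamma = gamma, base_score = base_score,
                 seed = as.integer(seed)),
            class = "gbt_config")
}

#' Gradient and Hessian of the logistic loss
#'
#' For binary log-loss at margin `m` with `p = sigmoid(m)`: the first
#' derivative is `g = p - y` and the second is `h = p (1 - p)`.
#'
#' @param labels 0/1 labels.
#' @param margins current additive margins (log-odds scale).
#' @return a list with vectors `g` and `h`.
#' @export
logistic_grad_hess <- function(labels, margins) {
  stopifnot(length(labels) == length(margins), all(is.finite(margins) | is.infinite(margins)))
  p <- sigmoid(margins)
  list(g = p - labels, h = p * (1 - p))
}

#' Newton leaf weight
#'
#' The optimal leaf value given summed gradients `G` and Hessians `H`:
#' `-G / (H + lambda)`.
#'
#' @param G,H summed first/second derivatives over the leaf's samples.
#' @param reg_lambda L2 regularization.
#' @return the leaf weight.
#' @export
leaf_weight <- function(G, H, reg_lambda = 1.0) {
  if (H + reg_lambda <= 0) stop("H + lambda must be > 0")
  -G / (H + reg_lambda)
}

#' Regularized structure score of a tree
#'
#' The minimized training objective of a tree with leaf statistics
#' `(G_j, H_j)`: `-1/2 sum_j G_j^2 / (H_j + lambda) + gamma * T` (the
#' constant term is omitted). Lower is better.
#'
#' @param G,H vectors of per-leaf summed gradients / Hessians.
#' @param reg_lambda,gamma regularization parameters.
#' @return the structure score.
#' @export
structure_score <- function(G, H, reg_lambda = 1.0, gamma = 0.0) {
  if (any(H + reg_lambda <= 0)) stop("H + lambda must be > 0")
  -0.5 * sum(G^2 / (H + reg_lambda)) + gamma * length(G)
}

#' Split gain
#'
#' The reduction in the regularized structure score from splitting a node
#' with children statistics `(G_L, H_L)` and `(G_R, H_R)`:
#' `1/2 [G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) -
#' (G_L+G_R)^2/(H_L+H_R+lambda)] - gamma`. Identical to
#' `structure_score(parent) - structure_score(children)`.
#'
#' @param G_L,H_L,G_R,H_R children gradient/Hessian sums.
#' @inheritParams structure_score
#' @return the gain (a split is kept only if this is > 0).
#' @export
split_gain <- function(G_L, H_L, G_R, H_R, reg_lambda = 1.0, gamma = 0.0) {
  if (H_L + reg_lambda <= 0 || H_R + reg_lambda <= 0)
    stop("H + lambda must be > 0")
  0.5 * (G_L^2 / (H_L + reg_lambda) + G_R^2 / (H_R + reg_lambda) -
           (G_L + G_R)^2 / (H_L + H_R + reg_lambda)) - gamma
}

#' Exact greedy best split of a node
#'
#' Enumerates every feature and every midpoint between consecutive
#' distinct sorted values; returns the maximum-gain candidate if its gain
#' is strictly positive, else `NULL`. Ties break toward the lower feature
#' index, then the lower threshold.
#'
#' @param x numeric matrix of the node's rows.
#' @param g,h per-row gradient / Hessian.
#' @inheritParams structure_score
#' @return `NULL`, or a list with `feature` (column index), `threshold`,
#'   `gain`, and the children sums `GL, HL, GR, HR`.
#' @export
best_split <- function(x, g, h, reg_lambda = 1.0, gamma = 0.0) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  res <- cpp_best_split(x, as.numeric(g), as.numeric(h), reg_lambda, gamma)
  if (!res$found) return(NULL)
  res$found <- NULL
  res
}

#' Fit a second-order boosted-tree classifier
#'
#' Gradient boosting for binary outcomes: each round computes per-sample
#' gradients and Hessians of the logistic loss at the current margins,
#' grows one regression tree by exact greedy search on the second-order
#' gain, assigns Newton leaf weights `-G/(H + lambda)`, and updates the
#' margins with shrinkage.
#'
#' @param x a numeric feature matrix, a `formula`, or a [labeled_table()].
#' @param ... passed to methods.
#' @return an object of class `gbt`: `trees` (list of node tables),
#'   `config`, `feature_names`, `base_margin`, and `train_logloss`
#'   (per-round training loss, non-increasing).
#' @examples
#' lt <- worked_fixture()
#' fit <- gbt(lt, config = gbt_config(n_estimators = 5, max_depth = 2))
#' predict(fit, lt$x, type = "class")
#' @export
gbt <- function(x, ...) UseMethod("gbt")

#' @param y 0/1 labels (default method).
#' @param config a [gbt_config()].
#' @rdname gbt
#' @export
gbt.default <- function(x, y, config = gbt_config(), ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (anyNA(x)) stop("missing cells: preprocess before fitting")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))

  base_margin <- stats::qlogis(config$base_score)
  margins <- rep(base_margin, nrow(x))
  trees <- vector("list", config$n_estimators)
  loss <- numeric(config$n_estimators)
  for (t in seq_len(config$n_estimators)) {
    gh <- logistic_grad_hess(y, margins)
    tr <- cpp_grow_tree(x, gh$g, gh$h, config$max_depth,
                        config$reg_lambda, config$gamma)
    trees[[t]] <- tr
    margins <- margins + config$learning_rate *
      cpp_predict_tree(x, tr$feature, tr$threshold, tr$weight,
                       tr$left, tr$right)
    p <- sigmoid(margins)
    loss[t] <- -mean(y * log(pmax(p, 1e-15)) +
                       (1 - y) * log(pmax(1 - p, 1e-15)))
  }
  structure(list(trees = trees, config = config,
                 feature_names = colnames(x), base_margin = base_margin,
                 train_logloss = loss),
            class = "gbt")
}

#' @param data a `data.frame` (formula method).
#' @rdname gbt
#' @export
gbt.formula <- function(x, data, config = gbt_config(), ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  xm <- stats::model.matrix(attr(mf, "terms"), mf)
  xm <- xm[, colnames(xm) != "(Intercept)", drop = FALSE]
  gbt.default(xm, y, config = config, ...)
}

#' @rdname gbt
#' @export
gbt.labeled_table <- function(x, config = gbt_config(), ...) {
  gbt.default(x$x, x$y, config = config, ...)
}

#' Predict from a boosted-tree model
#'
#' The margin of a sample is the base margin plus the shrinkage-scaled sum
#' of the leaf weights along its routing path in every tree; the
#' probability is the sigmoid of the margin; the class is 1 when the
#' probability reaches 0.5.
#'
#' @param object a fitted [gbt()] model.
#' @param newdata numeric matrix (or [labeled_table()]) with the training
#'   feature count.
#' @param type `"prob"` (default), `"margin"`, or `"class"`.
#' @param ... ignored.
#' @return a numeric (or integer, for `"class"`) vector.
#' @export
predict.gbt <- function(object, newdata, type = c("prob", "margin", "class"),
                        ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_table")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != length(object$feature_names))
    stop("feature count mismatch")
  m <- rep(object$base_margin, nrow(newdata))
  for (tr in object$trees)
    m <- m + object$config$learning_rate *
      cpp_predict_tree(newdata, tr$feature, tr$threshold, tr$weight,
                       tr$left, tr$right)
  switch(type, margin = m, prob = sigmoid(m),
         class = as.integer(sigmoid(m) >= 0.5))
}

#' @export
print.gbt <- function(x, ...) {
  cat(sprintf("<gbt> %d trees, max depth %d, eta %.2f, lambda %.2f; final train log-loss %.4f\n",
              length(x$trees), x$config$max_depth, x$config$learning_rate,
              x$config$reg_lambda, utils::tail(x$train_logloss, 1)))
  invisible(x)
}

#' @export
summary.gbt <- function(object, ...) {
  imp <- gain_importance(object)
  cat(sprintf("Second-order boosted-tree classifier: %d trees, depth <= %d\n",
              length(object$trees), object$config$max_depth))
  cat(sprintf("Training log-loss: %.4f -> %.4f over %d rounds\n",
              object$train_logloss[1], utils::tail(object$train_logloss, 1),
              length(object$train_logloss)))
  cat("Top features by average split gain:\n")
  print(utils::head(imp[imp$split_count > 0, ], 10))
  invisible(imp)
}

#' Gain-based feature importance
#'
#' For each feature, the average (and total) second-order split gain over
#' all internal nodes that split on it, across all trees. Features never
#' used score 0. The ranking sorts by average gain, descending, ties broken
#' by ascending feature index.
#'
#' @param model a fitted [gbt()] or [fit_easy_ensemble()] model; for an
#'   ensemble, split counts and gains are pooled over the balanced members
#'   before averaging.
#' @return a `data.frame` (class `gbt_importance`) with one row per
#'   feature in rank order: `feature`, `index`, `split_count`,
#'   `total_gain`, `average_gain`.
#' @export
gain_importance <- function(model) {
  trees <- if (inherits(model, "easy_ensemble"))
    unlist(lapply(model$members, `[[`, "trees"), recursive = FALSE)
  else model$trees
  p <- length(model$feature_names)
  cnt <- numeric(p); tot <- numeric(p)
  for (tr in trees) {
    internal <- tr$feature >= 0
    if (!any(internal)) next
    f <- tr$feature[internal] + 1L
    g <- tr$gain[internal]
    for (k in seq_along(f)) {
      cnt[f[k]] <- cnt[f[k]] + 1
      tot[f[k]] <- tot[f[k]] + g[k]
    }
  }
  avg <- ifelse(cnt > 0, tot / cnt, 0)
  ord <- order(-avg, seq_len(p))
  structure(data.frame(feature = model$feature_names[ord], index = ord,
                       split_count = cnt[ord], total_gain = tot[ord],
                       average_gain = avg[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("gbt_importance", "data.frame"))
}

#' Fit an EasyEnsemble of boosted-tree classifiers
#'
#' Handles class imbalance by training `n_members` models, each on all
#' minority-class samples plus an equal-sized random draw (without
#' replacement) of majority-class samples; the ensemble probability is the
#' arithmetic mean of member probabilities.
#'
#' @param x feature matrix or [labeled_table()].
#' @param y labels (ignored when `x` is a labeled table).
#' @param config a [gbt_config()].
#' @param n_members number of balanced members (default 10).
#' @param seed integer seed for the majority draws.
#' @return an object of class `easy_ensemble` with `members` (list of
#'   `gbt` fits) and `subsets` (majority row indices per member).
#' @export
fit_easy_ensemble <- function(x, y = NULL, config = gbt_config(),
                              n_members = 10, seed = 1L) {
  if (inherits(x, "labeled_table")) { y <- x$y; x <- x$x }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (min(n1, n0) == 0) stop("minority class is empty")
  if (min(n1, n0) < 2) stop("minority class needs >= 2 samples")
  minority <- if (n1 <= n0) 1L else 0L
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  members <- vector("list", n_members)
  subsets <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    draw <- if (length(maj_idx) <= length(min_idx)) maj_idx else
      sort(sample(maj_idx, length(min_idx)))
    rows <- c(min_idx, draw)
    subsets[[m]] <- draw
    members[[m]] <- gbt.default(x[rows, , drop = FALSE], y[rows], config)
  }
  structure(list(members = members, subsets = subsets,
                 feature_names = colnames(x)),
            class = "easy_ensemble")
}

#' @rdname fit_easy_ensemble
#' @param object a fitted `easy_ensemble`.
#' @param newdata feature matrix or [labeled_table()].
#' @param type `"prob"` (mean member probability) or `"class"`.
#' @param ... ignored.
#' @export
predict.easy_ensemble <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_table")) newdata <- newdata$x
  p <- rowMeans(vapply(object$members, predict, numeric(nrow(newdata)),
                       newdata = newdata, type = "prob"))
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
print.easy_ensemble <- function(x, ...) {
  cat(sprintf("<easy_ensemble> %d balanced members of %d trees each\n",
              length(x$members), length(x$members[[1]]$trees)))
  invisible(x)
}

#' Serialize / restore a boosted-tree model as JSON
#'
#' @param model a fitted [gbt()].
#' @param path output file.
#' @export
write_gbt_json <- function(model, path) {
  obj <- list(config = unclass(model$config),
              feature_names = model$feature_names,
              base_margin = model$base_margin,
              train_logloss = model$train_logloss,
              trees = lapply(model$trees, function(tr)
                lapply(tr, function(v) unname(v))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gbt_json
#' @export
read_gbt_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(if (is.data.frame(obj$trees)) nrow(obj$trees) else
    length(obj$trees)), function(i) {
      tr <- if (is.data.frame(obj$trees)) as.list(obj$trees[i, ]) else obj$trees[[i]]
      list(feature = as.integer(unlist(tr$feature)),
           threshold = as.numeric(unlist(tr$threshold)),
           weight = as.numeric(unlist(tr$weight)),
           gain = as.numeric(unlist(tr$gain)),
           left = as.integer(unlist(tr$left)),
           right = as.integer(unlist(tr$right)))
    })
  cfg <- do.call(gbt_config, obj$config[setdiff(names(obj$config), NULL)])
  structure(list(trees = trees, config = cfg,
                 feature_names = obj$feature_names,
                 base_margin = obj$base_margin,
                 train_logloss = obj$train_logloss),
            class = "gbt")
}

#' Two-score presentation of a binary prediction
#'
#' Renders a prediction in the "score for outcome occurrence vs score for
#' no occurrence" style used when boosted trees are drawn as one tree per
#' class: the occurrence score is the accumulated positive-class margin
#' contribution and the no-occurrence score its complement, so the class
#' with the larger score wins. Presentation utility only; the model itself
#' is a standard single-margin binary formulation.
#'
#' @param model a fitted [gbt()].
#' @param newdata feature matrix.
#' @return a `data.frame` with `score_outcome`, `score_no_outcome`, and the
#'   resulting `class`.
#' @export
two_score_view <- function(model, newdata) {
  m <- predict(model, newdata, type = "margin")
  data.frame(score_outcome = m, score_no_outcome = -m,
             class = as.integer(m >= 0))
}
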