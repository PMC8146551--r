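#' Tabu-search configuration
#'
#' The tuned values from the motivating study: candidate set length (CSL)
#' 20, tabu list length (TLL) 12, 200 iterations.
#'
#' @param csl candidate set length: single-flip neighbors evaluated per
#'   iteration (>= 1).
#' @param tll tabu list length: iterations a flipped feature stays
#'   forbidden, and the maximum number of active tabu entries (>= 0).
#' @param iterations fixed iteration budget (>= 1).
#' @param seed integer seed for neighbor sampling.
#' @return a list of class `tabu_config`.
#' @export
tabu_config <- function(csl = 20, tll = 12, iterations = 200, seed = 1L) {
  stopifnot(csl >= 1, tll >= 0, iterations >= 1)
  structure(list(csl = as.integer(csl), tll = as.integer(tll),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "tabu_config")
}

#' Bit-string solution encoding
#'
#' A feature subset as a 0/1 vector (`bits[i] = 1` iff feature i is
#' selected) tagged with the objective metric and the wrapped classifier.
#'
#' @param bits 0/1 vector with at least one bit set.
#' @param objective one of `"accuracy"`, `"precision"`, `"recall"`,
#'   `"f1"`, `"auc"`.
#' @param classifier text tag of the wrapped classifier.
#' @param score evaluation score in \[0, 1\], or `NA` if not yet scored.
#' @return a list of class `solution_encoding`.
#' @export
encode_solution <- function(bits, objective = "accuracy",
                            classifier = "gbt", score = NA_real_) {
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L)) || sum(bits) < 1)
    stop("bits must be 0/1 with at least one bit set")
  objective <- match.arg(objective,
                         c("accuracy", "precision", "recall", "f1", "auc"))
  structure(list(bits = bits, objective = objective,
                 classifier = classifier, score = score),
            class = "solution_encoding")
}

#' @export
print.solution_encoding <- function(x, ...) {
  cat(sprintf("<solution_encoding> %d/%d features, objective %s (%s), score %s\n",
              sum(x$bits), length(x$bits), x$objective, x$classifier,
              ifelse(is.na(x$score), "unset", sprintf("%.4f", x$score))))
  invisible(x)
}

#' Build a subset evaluator
#'
#' Returns a memoised function mapping a 0/1 feature-subset vector to a
#' scalar score in \[0, 1\]: the chosen metric of the wrapped classifier,
#' either by stratified k-fold cross-validation on the table (default) or
#' on the training data itself (`scheme = "train"`, the resubstitution
#' score used for the forward-search seeding step). Folds and ensemble
#' draws are fixed at creation, so the evaluator is deterministic: equal
#' subset, equal score, regardless of call order.
#'
#' @param table a preprocessed [labeled_table()].
#' @param metric objective tag (see [encode_solution()]).
#' @param config a [gbt_config()] for the wrapped classifier.
#' @param scheme `"cv"` or `"train"`.
#' @param k folds for `scheme = "cv"` (default 5 inside the search).
#' @param n_members EasyEnsemble members; 0 fits a single model.
#' @param seed integer seed (folds + ensemble draws).
#' @return a function `f(bits) -> score` with attributes `metric` and
#'   `classifier`.
#' @export
make_evaluator <- function(table, metric = "accuracy", config = gbt_config(),
                           scheme = c("cv", "train"), k = 5, n_members = 0,
                           seed = 1L) {
  scheme <- match.arg(scheme)
  metric <- match.arg(metric,
                      c("accuracy", "precision", "recall", "f1", "auc"))
  folds <- if (scheme == "cv") make_folds(table$y, k, seed) else NULL
  cache <- new.env(parent = emptyenv())
  fit_one <- function(x, y, member_seed) {
    if (n_members > 0)
      fit_easy_ensemble(x, y, config, n_members = n_members, seed = member_seed)
    else gbt.default(x, y, config)
  }
  f <- function(bits) {
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cols <- which(bits == 1L)
    score <- if (scheme == "train") {
      x <- table$x[, cols, drop = FALSE]
      fit <- fit_one(x, table$y, seed)
      pr <- predict(fit, x, type = "prob")
      compute_metrics(table$y, as.integer(pr >= 0.5), pr)[[metric]]
    } else {
      ms <- vapply(seq_len(k), function(fold) {
        tr <- folds != fold
        x_tr <- table$x[tr, cols, drop = FALSE]
        fit <- fit_one(x_tr, table$y[tr], seed + fold)
        pr <- predict(fit, table$x[!tr, cols, drop = FALSE], type = "prob")
        compute_metrics(table$y[!tr], as.integer(pr >= 0.5), pr)[[metric]]
      }, numeric(1))
      mean(ms)
    }
    cache[[key]] <- score
    score
  }
  attr(f, "metric") <- metric
  attr(f, "classifier") <- if (n_members > 0) "easy_ensemble(gbt)" else "gbt"
  f
}

#' Rank features by average split gain
#'
#' Fits one boosted-tree model on all features and returns its gain-based
#' importance ranking: the seeding step of the gain-sequence forward tabu
#' search.
#'
#' @param table a preprocessed [labeled_table()].
#' @param config a [gbt_config()].
#' @param n_members when > 0, rank by importance pooled over an
#'   EasyEnsemble of this many balanced members instead of a single fit —
#'   the appropriate choice on strongly imbalanced cohorts.
#' @param seed seed for the ensemble draws.
#' @return a `gbt_importance` ranking (see [gain_importance()]).
#' @export
rank_by_gain <- function(table, config = gbt_config(), n_members = 0,
                         seed = 1L) {
  fit <- if (n_members > 0)
    fit_easy_ensemble(table, config = config, n_members = n_members,
                      seed = seed)
  else gbt.labeled_table(table, config = config)
  gain_importance(fit)
}

#' Gain-ranked sequential forward search
#'
#' Starting from the top-ranked feature, features are added in descending
#' importance order; the search stops when the evaluation score strictly
#' drops and returns the subset before the drop (ties continue).
#'
#' @param ranking a `gbt_importance` ranking from [rank_by_gain()].
#' @param evaluator an evaluator from [make_evaluator()].
#' @return a [encode_solution()] with the achieved score; the per-step
#'   scores are attached as attribute `"path"`.
#' @export
gain_sfs <- function(ranking, evaluator) {
  stopifnot(nrow(ranking) >= 1)
  n <- nrow(ranking)
  bits <- integer(n)
  bits[ranking$index[1]] <- 1L
  best <- evaluator(bits)
  path <- best
  i <- 1
  while (i < n) {
    cand <- bits
    cand[ranking$index[i + 1]] <- 1L
    s <- evaluator(cand)
    path <- c(path, s)
    if (s < best) break
    bits <- cand
    best <- s
    i <- i + 1
  }
  out <- encode_solution(bits, attr(evaluator, "metric"),
                         attr(evaluator, "classifier"), best)
  attr(out, "path") <- path
  out
}

#' Propose single-flip neighbors
#'
#' Up to `csl` encodings each differing from the current solution in
#' exactly one bit; flipped positions are drawn uniformly without
#' replacement, a flip that would empty the subset is infeasible, and if
#' `csl` meets or exceeds the number of feasible flips all of them are
#' returned.
#'
#' @param bits current 0/1 subset vector.
#' @param csl candidate set length.
#' @return a list of neighbors, each a list with `bits` and `flipped`
#'   (the flipped feature index).
#' @export
propose_neighbors <- function(bits, csl) {
  feasible <- seq_along(bits)
  if (sum(bits) == 1L) feasible <- feasible[bits != 1L]
  pick <- if (csl >= length(feasible)) feasible else
    sort(sample(feasible, csl))
  lapply(pick, function(j) {
    nb <- bits
    nb[j] <- 1L - nb[j]
    list(bits = nb, flipped = j)
  })
}

new_tabu_state <- function(init_bits, init_score) {
  list(current_bits = init_bits, current_score = init_score,
       best_bits = init_bits, best_score = init_score,
       tabu = integer(0),  # named vector: feature index -> remaining tenure
       trace = list())
}

#' One tabu-search iteration
#'
#' Scores every neighbor; a neighbor is admissible when its flipped
#' feature is not on the tabu list, or when its score strictly beats the
#' best solution found so far (aspiration / contempt rule). The best
#' admissible neighbor becomes the current solution even if it is worse
#' than the incumbent; its flipped feature enters the tabu list with
#' tenure `tll`, all tenures decay by one per iteration, and at most
#' `tll` entries stay active (oldest evicted). If no neighbor is
#' admissible the best tabu neighbor is taken (least remaining tenure,
#' then lowest index) and flagged in the trace.
#'
#' @param state a tabu state as produced by [gsfts()] internals (list with
#'   current/best bits and scores, tabu tenures, trace).
#' @param neighbors output of [propose_neighbors()].
#' @param evaluator an evaluator from [make_evaluator()].
#' @param tll tabu list length.
#' @return the updated state.
#' @export
tabu_iteration <- function(state, neighbors, evaluator, tll) {
  stopifnot(length(neighbors) >= 1)
  scores <- vapply(neighbors, function(nb) evaluator(nb$bits), numeric(1))
  flipped <- vapply(neighbors, `[[`, integer(1), "flipped")
  is_tabu <- as.character(flipped) %in% names(state$tabu)
  aspire <- scores > state$best_score
  admissible <- !is_tabu | aspire

  if (any(admissible)) {
    idx <- which(admissible)
    pick <- idx[order(-scores[idx], flipped[idx])[1]]
    blocked <- FALSE
  } else {
    tenure <- state$tabu[as.character(flipped)]
    pick <- order(-scores, tenure, flipped)[1]
    blocked <- TRUE
  }
  aspiration_used <- is_tabu[pick] && aspire[pick]

  state$current_bits <- neighbors[[pick]]$bits
  state$current_score <- scores[pick]
  if (scores[pick] > state$best_score) {
    state$best_score <- scores[pick]
    state$best_bits <- neighbors[[pick]]$bits
  }
  # age existing entries, then add the chosen flip with full tenure
  state$tabu <- state$tabu - 1L
  state$tabu <- state$tabu[state$tabu > 0L]
  if (tll > 0) {
    state$tabu <- state$tabu[names(state$tabu) != as.character(flipped[pick])]
    state$tabu <- c(state$tabu, stats::setNames(as.integer(tll),
                                                as.character(flipped[pick])))
    if (length(state$tabu) > tll)  # oldest = smallest remaining tenure
      state$tabu <- state$tabu[order(-state$tabu)][seq_len(tll)]
  }
  state$trace[[length(state$trace) + 1]] <- data.frame(
    iteration = length(state$trace) + 1L, flipped = flipped[pick],
    n_candidates = length(neighbors), current_score = scores[pick],
    best_score = state$best_score, tabu_blocked = blocked,
    aspiration_used = aspiration_used)
  state
}

#' Gain-sequence forward tabu search feature selection
#'
#' The full wrapper selector: (1) rank features by average split gain of a
#' boosted-tree fit on all features; (2) seed with a gain-ranked
#' sequential forward search; (3) refine by tabu search over single-bit
#' flips with candidate sets, tabu tenure and an aspiration rule, for a
#' fixed number of iterations. The returned best-so-far solution never
#' scores below the forward-search seed.
#'
#' @param table a preprocessed [labeled_table()].
#' @param objective metric to maximize (`"accuracy"`, `"precision"`,
#'   `"recall"`, `"f1"`, `"auc"`).
#' @param gbt_config a [gbt_config()] for the wrapped classifier.
#' @param tabu_config a [tabu_config()].
#' @param n_members EasyEnsemble members used for both the gain ranking
#'   and the subset evaluator (0 = single model; use > 0 on imbalanced
#'   cohorts).
#' @param evaluator optional evaluator from [make_evaluator()]; built from
#'   `table`, `objective` and `gbt_config` with the `...` options if
#'   omitted.
#' @param ... passed to [make_evaluator()] (e.g. `scheme`, `k`).
#' @return an object of class `gsfts`: `encoding` (best solution),
#'   `initial` (the forward-search seed), `ranking`, `trace` (one row per
#'   iteration), and the configurations.
#' @examples
#' cohort <- generate_cohort(cohort_spec(200, 12, missing_rate = 0,
#'                                       outlier_rate = 0), seed = 7)
#' sel <- gsfts(cohort$table, objective = "accuracy",
#'              gbt_config = gbt_config(n_estimators = 10, max_depth = 2),
#'              tabu_config = tabu_config(csl = 4, tll = 3, iterations = 5),
#'              k = 3)
#' summary(sel)
#' @export
gsfts <- function(table, objective = "accuracy", gbt_config = gbt_config(),
                  tabu_config = tabu_config(), n_members = 0,
                  evaluator = NULL, ...) {
  if (is.null(evaluator))
    evaluator <- make_evaluator(table, metric = objective, config = gbt_config,
                                n_members = n_members,
                                seed = tabu_config$seed, ...)
  ranking <- rank_by_gain(table, gbt_config, n_members = n_members,
                          seed = tabu_config$seed)
  initial <- gain_sfs(ranking, evaluator)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(tabu_config$seed, "tabu"))

  state <- new_tabu_state(initial$bits, initial$score)
  for (it in seq_len(tabu_config$iterations)) {
    nb <- propose_neighbors(state$current_bits, tabu_config$csl)
    state <- tabu_iteration(state, nb, evaluator, tabu_config$tll)
  }
  trace <- do.call(rbind, state$trace)
  structure(list(
    encoding = encode_solution(state$best_bits, attr(evaluator, "metric"),
                               attr(evaluator, "classifier"),
                               state$best_score),
    initial = initial, ranking = ranking, trace = trace,
    gbt_config = gbt_config, tabu_config = tabu_config,
    feature_names = colnames(table$x)),
    class = "gsfts")
}

#' @export
print.gsfts <- function(x, ...) {
  cat(sprintf("<gsfts> selected %d/%d features; %s = %.4f (seed search %.4f) after %d tabu iterations\n",
              sum(x$encoding$bits), length(x$encoding$bits),
              x$encoding$objective, x$encoding$score, x$initial$score,
              nrow(x$trace)))
  invisible(x)
}

#' @export
summary.gsfts <- function(object, ...) {
  print(object)
  sel <- which(object$encoding$bits == 1L)
  cat("Selected features:", paste(object$feature_names[sel], collapse = ", "),
      "\n")
  cat(sprintf("Aspiration used in %d iterations; all-tabu fallback in %d\n",
              sum(object$trace$aspiration_used),
              sum(object$trace$tabu_blocked)))
  invisible(object)
}

#' @param x a `gsfts` object.
#' @param ... ignored.
#' @rdname gsfts
#' @export
plot.gsfts <- function(x, ...) {
  plot(x$trace$iteration, x$trace$current_score, type = "l", col = "grey50",
       xlab = "tabu iteration", ylab = x$encoding$objective,
       ylim = range(c(x$trace$current_score, x$trace$best_score)),
       main = "Tabu search progress")
  graphics::lines(x$trace$iteration, x$trace$best_score, col = "firebrick",
                  lwd = 2)
  graphics::abline(h = x$initial$score, lty = 2)
  graphics::legend("bottomright", c("current", "best-so-far", "seed"),
                   col = c("grey50", "firebrick", "black"),
                   lty = c(1, 1, 2), lwd = c(1, 2, 1), bty = "n")
  invisible(x)
}

#' Recursive feature elimination baseline
#'
#' Repeatedly refits the boosted-tree model, drops the feature with the
#' lowest average split gain, and finally keeps the subset size whose
#' evaluator score is best (ties keep the earlier, larger subset).
#'
#' @param table a preprocessed [labeled_table()].
#' @param evaluator an evaluator from [make_evaluator()].
#' @param config a [gbt_config()] used for the refits.
#' @param min_size smallest subset size to reach (default 1).
#' @return a [encode_solution()]; the elimination path (size, dropped
#'   feature, score) is attached as attribute `"path"`.
#' @export
run_rfe <- function(table, evaluator, config = gbt_config(), min_size = 1) {
  n <- ncol(table$x)
  bits <- rep(1L, n)
  best_bits <- bits
  best_score <- evaluator(bits)
  path <- data.frame(size = n, dropped = NA_integer_, score = best_score)
  while (sum(bits) > min_size) {
    cols <- which(bits == 1L)
    fit <- gbt.default(table$x[, cols, drop = FALSE], table$y, config)
    imp <- gain_importance(fit)
    drop_local <- imp$index[nrow(imp)]  # lowest average gain, tie: highest index
    bits[cols[drop_local]] <- 0L
    s <- evaluator(bits)
    path <- rbind(path, data.frame(size = sum(bits),
                                   dropped = cols[drop_local], score = s))
    if (s > best_score) { best_score <- s; best_bits <- bits }
  }
  out <- encode_solution(best_bits, attr(evaluator, "metric"),
                         attr(evaluator, "classifier"), best_score)
  attr(out, "path") <- path
  out
}

#' Plain sequential forward search baseline
#'
#' Greedy forward selection over all remaining features (not gain-ordered):
#' at each step every candidate addition is scored and the best is taken;
#' the search stops when the best addition strictly drops the score.
#'
#' @inheritParams run_rfe
#' @return a [encode_solution()].
#' @export
run_plain_sfs <- function(table, evaluator) {
  n <- ncol(table$x)
  bits <- integer(n)
  current <- -Inf
  repeat {
    remaining <- which(bits == 0L)
    if (length(remaining) == 0) break
    scores <- vapply(remaining, function(j) {
      cand <- bits
      cand[j] <- 1L
      evaluator(cand)
    }, numeric(1))
    best_j <- remaining[order(-scores, remaining)[1]]
    best_s <- max(scores)
    if (best_s < current) break
    bits[best_j] <- 1L
    current <- best_s
  }
  encode_solution(bits, attr(evaluator, "metric"),
                  attr(evaluator, "classifier"), current)
}
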