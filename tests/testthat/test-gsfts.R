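test_that("gain ranking finds the lone predictive feature", {
  set.seed(21)
  x <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(x[, 2] > 0.5)
  tab <- labeled_table(x, y)
  imp <- rank_by_gain(tab, quick_gbt(5, 2))
  expect_equal(imp$feature[1], "b")

  # gamma high enough that nothing splits: all gains 0, index tie-break
  imp0 <- rank_by_gain(tab, gbt_config(n_estimators = 3, max_depth = 2,
                                       gamma = 1e6))
  expect_true(all(imp0$average_gain == 0))
  expect_equal(imp0$index, 1:3)
  expect_setequal(imp$index, 1:3)  # ranking is a permutation
})

test_that("gain-ranked forward search follows the documented stop rule", {
  rk <- fake_ranking(c(3, 1, 4, 2))

  # monotone evaluator (subset size / n): never drops, takes everything
  mono <- planted_evaluator(list(), default = 0)
  mono_f <- function(bits) sum(bits) / length(bits)
  attributes(mono_f) <- attributes(mono)
  expect_equal(sum(gain_sfs(rk, mono_f)$bits), 4)

  # immediate drop: keeps the top-1 subset
  ev <- planted_evaluator(list("3" = 0.8, "1,3" = 0.7))
  res <- gain_sfs(rk, ev)
  expect_equal(which(res$bits == 1L), 3L)
  expect_equal(res$score, 0.8)

  # planted path 0.6, 0.7, 0.7, 0.65: ties continue, stops before the drop
  ev2 <- planted_evaluator(list("3" = 0.6, "1,3" = 0.7, "1,3,4" = 0.7,
                                "1,2,3,4" = 0.65))
  res2 <- gain_sfs(rk, ev2)
  expect_setequal(which(res2$bits == 1L), c(3L, 1L, 4L))
  expect_equal(res2$score, 0.7)
  expect_equal(attr(res2, "path"), c(0.6, 0.7, 0.7, 0.65))
})

test_that("neighbors are single flips that never empty the subset", {
  set.seed(5)
  bits <- c(1L, 0L, 1L, 0L, 1L)
  nb <- propose_neighbors(bits, csl = 30)
  expect_lte(length(nb), 5)
  expect_equal(length(unique(vapply(nb, `[[`, integer(1), "flipped"))),
               length(nb))
  for (n in nb) {
    expect_equal(sum(n$bits != bits), 1L)   # Hamming distance exactly 1
    expect_gte(sum(n$bits), 1L)
  }

  lone <- c(0L, 1L, 0L)
  nb2 <- propose_neighbors(lone, csl = 10)
  expect_length(nb2, 2)
  expect_true(all(vapply(nb2, function(n) sum(n$bits), integer(1)) == 2L))

  nb3 <- propose_neighbors(bits, csl = 2)
  expect_length(nb3, 2)
})

test_that("tabu tenure blocks a flipped feature for exactly TLL iterations", {
  # four fixed neighbors; feature 2 scores best but the incumbent best
  # (1.0) is unreachable, so aspiration never fires
  bits <- c(1L, 1L, 1L, 1L, 1L, 0L)
  mk_nb <- function() lapply(2:5, function(j) {
    nb <- bits; nb[j] <- 0L; list(bits = nb, flipped = j)
  })
  scores <- c("2" = 0.9, "3" = 0.1, "4" = 0.2, "5" = 0.3)
  ev <- function(b) unname(scores[as.character(which(bits != b))])
  attr(ev, "metric") <- "accuracy"; attr(ev, "classifier") <- "planted"

  state <- gsfts:::new_tabu_state(bits, 1.0)
  for (i in 1:5) state <- tabu_iteration(state, mk_nb(), ev, tll = 3)
  flips <- vapply(state$trace, `[[`, numeric(1), "flipped")
  # flipped at iter 1, inadmissible at 2,3,4, admissible (and best) at 5
  expect_equal(flips, c(2, 5, 4, 3, 2))
})

test_that("TLL = 0 disables the tabu list; aspiration overrides it", {
  bits <- c(1L, 1L, 0L)
  nb <- list(list(bits = c(1L, 0L, 0L), flipped = 2L))
  ev <- function(b) 0.4
  attr(ev, "metric") <- "accuracy"; attr(ev, "classifier") <- "planted"
  state <- gsfts:::new_tabu_state(bits, 0.5)
  for (i in 1:3) {
    state <- tabu_iteration(state, nb, ev, tll = 0)
    expect_length(state$tabu, 0)
    expect_false(state$trace[[i]]$tabu_blocked)
  }

  # a tabu neighbor beating the best-so-far is selected via aspiration
  state2 <- gsfts:::new_tabu_state(bits, 0.5)
  ev_up <- local({
    calls <- 0
    f <- function(b) {
      calls <<- calls + 1
      0.4 + 0.1 * calls  # strictly improving scores
    }
    attr(f, "metric") <- "accuracy"; attr(f, "classifier") <- "planted"
    f
  })
  state2 <- tabu_iteration(state2, nb, ev_up, tll = 5)   # flips 2, now tabu
  state2 <- tabu_iteration(state2, nb, ev_up, tll = 5)   # tabu but improving
  expect_true(state2$trace[[2]]$aspiration_used)
  expect_false(state2$trace[[2]]$tabu_blocked)
})

test_that("full search keeps its guarantees on seeded cohorts", {
  for (s in 1:3) {
    tab <- small_cohort(150, 10, seed = s, preprocessed = TRUE)
    fit <- gsfts(tab, objective = "accuracy",
                 gbt_config = quick_gbt(8, 2),
                 tabu_config = tabu_config(csl = 4, tll = 3, iterations = 8,
                                           seed = s),
                 k = 3)
    # best-so-far is non-decreasing
    expect_true(all(diff(fit$trace$best_score) >= 0))
    # the tabu phase never scores below its forward-search seed
    expect_gte(fit$encoding$score, fit$initial$score)
    # the forward-search seed is a prefix of the gain ranking
    k <- sum(fit$initial$bits)
    expect_setequal(which(fit$initial$bits == 1L), fit$ranking$index[1:k])
  }
})

test_that("identical data, config and seed give identical traces", {
  tab <- small_cohort(120, 8, seed = 4, preprocessed = TRUE)
  args <- list(tab, objective = "accuracy", gbt_config = quick_gbt(6, 2),
               tabu_config = tabu_config(csl = 3, tll = 2, iterations = 6,
                                         seed = 11), k = 3)
  a <- do.call(gsfts, args)
  b <- do.call(gsfts, args)
  expect_identical(a$trace, b$trace)
  expect_identical(a$encoding, b$encoding)

  # minimal run: one iteration, one candidate
  m <- gsfts(tab, gbt_config = quick_gbt(4, 2),
             tabu_config = tabu_config(csl = 1, tll = 1, iterations = 1,
                                       seed = 2), k = 3)
  expect_equal(nrow(m$trace), 1L)
})

test_that("tabu discipline holds in every iteration of a real run", {
  tab <- small_cohort(150, 10, seed = 6, preprocessed = TRUE)
  fit <- gsfts(tab, gbt_config = quick_gbt(6, 2),
               tabu_config = tabu_config(csl = 5, tll = 3, iterations = 12,
                                         seed = 3), k = 3)
  tr <- fit$trace
  # a chosen flip is either non-tabu, an aspiration move, or an explicit
  # all-tabu fallback; reconstruct tenures to verify
  tabu <- integer(0)
  best <- fit$initial$score
  ok <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    f <- as.character(tr$flipped[i])
    ok[i] <- tr$tabu_blocked[i] || !(f %in% names(tabu)) ||
      tr$aspiration_used[i] || tr$current_score[i] > best
    best <- max(best, tr$current_score[i])
    tabu <- tabu - 1L
    tabu <- tabu[tabu > 0L]
    tabu <- tabu[names(tabu) != f]
    tabu <- c(tabu, stats::setNames(3L, f))
    if (length(tabu) > 3) tabu <- tabu[order(-tabu)][1:3]
  }
  expect_true(all(ok))
})

test_that("RFE eliminates the weakest feature at each refit", {
  # y driven by f1 (strong) and f2 (weaker); f3 pure noise
  set.seed(31)
  n <- 200
  x <- cbind(f1 = runif(n), f2 = runif(n), f3 = runif(n))
  y <- as.integer((2.5 * x[, "f1"] + 1 * x[, "f2"]) > 1.75)
  tab <- labeled_table(x, y)
  ev <- make_evaluator(tab, "accuracy", quick_gbt(8, 2), k = 3, seed = 1)
  res <- run_rfe(tab, ev, quick_gbt(8, 2))
  path <- attr(res, "path")
  expect_equal(path$size, c(3, 2, 1))
  expect_equal(path$dropped[-1], c(3L, 2L))  # noise out first, then weaker
  expect_gte(sum(res$bits), 1)

  # the sole survivor at each refit is the top-gain feature
  imp_full <- rank_by_gain(tab, quick_gbt(8, 2))
  expect_equal(imp_full$index[1], 1L)
})

test_that("plain forward search stops only on a strict drop", {
  mono <- function(bits) sum(bits) / length(bits)
  attr(mono, "metric") <- "accuracy"; attr(mono, "classifier") <- "planted"
  tab <- small_cohort(60, 5, seed = 2)
  res <- run_plain_sfs(tab, mono)
  expect_equal(sum(res$bits), 5)

  ev <- make_evaluator(tab, "accuracy", quick_gbt(5, 2), k = 3, seed = 1)
  res2 <- run_plain_sfs(tab, ev)
  expect_s3_class(res2, "solution_encoding")
  expect_gte(sum(res2$bits), 1)
})
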