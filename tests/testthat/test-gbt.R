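test_that("logistic gradients and Hessians match finite differences", {
  # loss(m) = -y log p - (1-y) log(1-p); oracle: central differences
  loss <- function(y, m) {
    p <- 1 / (1 + exp(-m))
    -(y * log(p) + (1 - y) * log(1 - p))
  }
  eps <- 1e-5
  for (y in c(0, 1)) for (m in c(-1.3, 0, 0.7)) {
    gh <- logistic_grad_hess(y, m)
    g_num <- (loss(y, m + eps) - loss(y, m - eps)) / (2 * eps)
    h_num <- (loss(y, m + eps) - 2 * loss(y, m) + loss(y, m - eps)) / eps^2
    expect_equal(gh$g, g_num, tolerance = 1e-6)
    expect_equal(gh$h, h_num, tolerance = 1e-4)
  }
  expect_equal(logistic_grad_hess(0, 0), list(g = 0.5, h = 0.25))
  # saturated correct prediction: both derivatives vanish
  sat <- logistic_grad_hess(1, 40)
  expect_lt(abs(sat$g), 1e-15)
  expect_lt(sat$h, 1e-15)
  # class-balanced set at margin 0 sums to zero gradient
  gh <- logistic_grad_hess(rep(c(0, 1), 10), rep(0, 20))
  expect_equal(sum(gh$g), 0)
})

test_that("leaf weight is the Newton step, matching numeric minimization", {
  expect_equal(leaf_weight(0, 5, 1), 0)
  # oracle: minimize G*w + 1/2 (H + lambda) w^2 numerically
  opt <- stats::optimize(function(w) 2 * w + 0.5 * (3 + 1) * w^2, c(-5, 5))
  expect_equal(leaf_weight(2, 3, 1), opt$minimum, tolerance = 1e-5)
  expect_equal(leaf_weight(2, 3, 1), -0.5)
  expect_lt(abs(leaf_weight(2, 3, 1e9)), 1e-8)  # lambda -> Inf shrinks to 0
  expect_error(leaf_weight(1, -2, 1), "> 0")
})

test_that("structure score and split gain satisfy their identities", {
  expect_equal(structure_score(0, 3, 1, gamma = 0.7), 0.7)
  expect_equal(structure_score(c(2, -2), c(3, 3), 1, 0), -1.0)
  expect_equal(split_gain(1, 2, 1, 2, 0, 0), 0)  # symmetric split: no gain
  expect_equal(split_gain(2, 2, -2, 2, 0, 0), 2.0)
  g0 <- split_gain(3, 1, -1, 2, 0.5, 0)
  expect_equal(split_gain(3, 1, -1, 2, 0.5, gamma = g0), 0)

  # oracle equivalence on random node configurations: gain equals
  # parent structure score minus children structure score
  set.seed(101)
  for (i in 1:200) {
    GL <- rnorm(1, 0, 3); GR <- rnorm(1, 0, 3)
    HL <- runif(1, 0.01, 5); HR <- runif(1, 0.01, 5)
    lam <- runif(1, 0, 2); gam <- runif(1, 0, 1)
    expect_equal(
      split_gain(GL, HL, GR, HR, lam, gam),
      structure_score(GL + GR, HL + HR, lam, gam) -
        structure_score(c(GL, GR), c(HL, HR), lam, gam),
      tolerance = 1e-9)
  }
})

test_that("squared-loss limit: single leaf weight is sum(residuals)/(n+lambda)", {
  set.seed(7)
  y <- rnorm(30); yhat <- rnorm(30)
  g <- yhat - y; h <- rep(1, 30)
  lam <- 1.5
  expect_equal(leaf_weight(sum(g), sum(h), lam), sum(y - yhat) / (30 + lam))
})

test_that("exact greedy split: fixture, order invariance, degenerate cases", {
  lt <- worked_fixture()
  gh <- logistic_grad_hess(lt$y, rep(0, 12))
  sp <- best_split(lt$x, gh$g, gh$h)
  expect_equal(sp$feature, 1L)
  # children sums partition the parent's G, H
  expect_equal(sp$GL + sp$GR, sum(gh$g))
  expect_equal(sp$HL + sp$HR, sum(gh$h))
  # gain equals the structure-score difference
  expect_equal(sp$gain,
               structure_score(sp$GL + sp$GR, sp$HL + sp$HR, 1, 0) -
                 structure_score(c(sp$GL, sp$GR), c(sp$HL, sp$HR), 1, 0),
               tolerance = 1e-9)

  perm <- sample(12)
  sp2 <- best_split(lt$x[perm, ], gh$g[perm], gh$h[perm])
  expect_equal(sp2[c("feature", "threshold", "gain")],
               sp[c("feature", "threshold", "gain")])

  # all labels equal: every g has the same sign, no positive gain
  gh0 <- logistic_grad_hess(rep(1, 12), rep(0, 12))
  expect_null(best_split(lt$x, gh0$g, gh0$h))
})

test_that("boosting is deterministic with non-increasing training loss", {
  lt <- small_cohort(150, 8, seed = 3)
  cfg <- quick_gbt(n_estimators = 15, max_depth = 3)
  f1 <- gbt(lt, config = cfg)
  f2 <- gbt(lt, config = cfg)
  expect_identical(f1$trees, f2$trees)
  expect_true(all(diff(f1$train_logloss) <= 1e-12))

  # minimal model: one stump
  stump <- gbt(worked_fixture(), config = quick_gbt(1, 1))
  expect_length(stump$trees, 1)
  expect_equal(sum(stump$trees[[1]]$feature >= 0), 1L)

  expect_error(gbt_config(n_estimators = 0))
  expect_error(gbt(labeled_table(matrix(rnorm(10), 5, 2), rep(1L, 5)),
                   config = quick_gbt()), "class")
  xna <- matrix(c(NA, rnorm(9)), 5, 2)
  expect_error(gbt(labeled_table(xna, rep(c(0L, 1L), c(2, 3))),
                   config = quick_gbt()), "missing")
})

test_that("prediction is the shrinkage-scaled sum of routed leaf weights", {
  # hand-built model: two stumps whose leaves are 2.5 and 1.5 for a row
  # routed right/right; eta = 1, base probability 0.5 (margin 0)
  stump <- function(w_left, w_right) list(
    feature = c(0L, -1L, -1L), threshold = c(0.5, NA, NA),
    weight = c(NA, w_left, w_right), gain = c(1, NA, NA),
    left = c(2L, 0L, 0L), right = c(3L, 0L, 0L))
  model <- structure(list(
    trees = list(stump(-1, 2.5), stump(-2, 1.5)),
    config = gbt_config(n_estimators = 2, learning_rate = 1),
    feature_names = "f", base_margin = 0, train_logloss = c(0, 0)),
    class = "gbt")
  expect_equal(predict(model, matrix(0.9), type = "margin"), 4.0)
  expect_equal(predict(model, matrix(0.9), type = "prob"), stats::plogis(4))
  expect_equal(predict(model, matrix(0.1), type = "margin"), -3.0)

  # empty tree list: probability is sigmoid(base margin) everywhere
  empty <- model
  empty$trees <- list()
  expect_equal(predict(empty, matrix(c(0.1, 0.9), 2), type = "prob"),
               rep(0.5, 2))

  # a deep single tree separates the separable fixture perfectly
  lt <- worked_fixture()
  deep <- gbt(lt, config = gbt_config(n_estimators = 1, max_depth = 6,
                                      learning_rate = 1))
  expect_identical(predict(deep, lt$x, type = "class"), lt$y)

  expect_error(predict(deep, matrix(0, 1, 7)), "mismatch")
})

test_that("gain importance aggregates split gains and ranks correctly", {
  lt <- worked_fixture()
  stump <- gbt(lt, config = quick_gbt(1, 1))
  imp <- gain_importance(stump)
  expect_equal(imp$feature[1], "SEP")
  expect_equal(imp$split_count[1], 1)
  expect_equal(imp$average_gain[1], imp$total_gain[1])
  expect_true(all(imp$average_gain[-1] == 0))
  # unused features tie at 0 and keep ascending index order
  expect_equal(imp$index[-1], sort(imp$index[-1]))

  fit <- gbt(small_cohort(200, 10, seed = 5), config = quick_gbt(10, 3))
  imp2 <- gain_importance(fit)
  all_gains <- unlist(lapply(fit$trees, function(tr) tr$gain[tr$feature >= 0]))
  expect_equal(sum(imp2$total_gain), sum(all_gains))
})

test_that("informative features rank above noise on synthetic cohorts", {
  spec <- cohort_spec(2000, 84, missing_rate = 0, outlier_rate = 0)
  inf <- which(spec$features$informative)
  gaps <- vapply(1:5, function(s) {
    tab <- generate_cohort(spec, seed = s)$table
    imp <- rank_by_gain(preprocess(tab)$table,
                        gbt_config(n_estimators = 20, max_depth = 3))
    rank_of <- match(seq_len(84), imp$index)
    mean(rank_of[-inf]) - mean(rank_of[inf])
  }, numeric(1))
  expect_true(all(gaps > 0))
})

test_that("EasyEnsemble members are balanced and averaging helps recall", {
  tab <- small_cohort(320, 10, seed = 8)
  ens <- fit_easy_ensemble(tab, config = quick_gbt(10, 2), n_members = 5,
                           seed = 2)
  for (m in seq_along(ens$members)) {
    draw <- ens$subsets[[m]]
    expect_equal(length(draw), sum(tab$y == 1))
    expect_true(all(tab$y[draw] == 0))
    expect_equal(length(unique(draw)), length(draw))  # without replacement
  }

  # degenerate draw: balanced data with one member = plain fit
  bal <- labeled_table(matrix(rnorm(80), 40, 2), rep(c(0L, 1L), 20))
  e1 <- fit_easy_ensemble(bal, config = quick_gbt(5, 2), n_members = 1)
  single <- gbt(bal$x[c(which(bal$y == 1), which(bal$y == 0)), ],
                bal$y[c(which(bal$y == 1), which(bal$y == 0))],
                config = quick_gbt(5, 2))
  expect_equal(predict(e1, bal$x), predict(single, bal$x))

  expect_error(fit_easy_ensemble(labeled_table(matrix(rnorm(10), 5, 2),
                                               rep(0L, 5))), "minority")

  # 1:7 cohorts: mean ensemble recall >= mean single-model recall
  rec <- vapply(1:5, function(s) {
    train <- small_cohort(320, 10, seed = 10 + s)
    test <- small_cohort(800, 10, seed = 100 + s)
    cfg <- quick_gbt(10, 2)
    ens <- fit_easy_ensemble(train, config = cfg, n_members = 5, seed = s)
    one <- gbt(train, config = cfg)
    c(ens = compute_metrics(test$y, predict(ens, test$x, type = "class"),
                            predict(ens, test$x))$recall,
      one = compute_metrics(test$y, predict(one, test$x, type = "class"),
                            predict(one, test$x))$recall)
  }, numeric(2))
  expect_gte(mean(rec["ens", ]), mean(rec["one", ]))
})

test_that("model JSON round-trips with identical predictions", {
  lt <- small_cohort(100, 6, seed = 4)
  fit <- gbt(lt, config = quick_gbt(5, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_gbt_json(fit, path)
  back <- read_gbt_json(path)
  expect_equal(predict(back, lt$x), predict(fit, lt$x))

  ts <- two_score_view(fit, lt$x)
  expect_equal(ts$score_outcome + ts$score_no_outcome, rep(0, 100))
  expect_identical(ts$class, predict(fit, lt$x, type = "class"))
})
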