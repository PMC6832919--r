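test_that("MAE follows its defining formula", {
  expect_equal(mae(c(3, 2, 4), c(3, 2, 4)), 0)
  expect_equal(mae(c(0, 4), c(4, 0)), 4)
  expect_equal(mae(c(3, 1, 2, 0), c(1, 2, 4, 1)), 1.5)
  expect_error(mae(1:3, 1:4), class = "alsord_config_error")
})

test_that("the median decision minimises expected absolute error", {
  set.seed(8)
  for (i in 1:50) {
    p <- runif(5); p <- p / sum(p)
    probs <- matrix(p, 1, dimnames = list(NULL, 0:4))
    m <- distribution_median(probs)
    risks <- vapply(0:4, function(c) sum(p * abs(0:4 - c)), numeric(1))
    expect_lte(risks[m + 1], min(risks) + 1e-12)
  }
})

sim_ordinal_table <- function(n, seed = 1, noise = 0.6) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    w <- rnorm(n)
    y <- pmin(pmax(round(2 + 1.2 * z - 0.8 * w + rnorm(n, 0, noise)), 0), 4)
    tibble::tibble(z = z, w = w, n1 = rnorm(n), target = as.integer(y))
  })
}

test_that("intercept-only CLM reproduces the empirical marginal", {
  d <- sim_ordinal_table(300, seed = 2)
  fit <- fit_clm(d, features = character(0))
  p <- predict(fit, d[1:5, ], type = "prob")
  marg <- as.numeric(table(factor(d$target, levels = 0:4)) / nrow(d))
  for (i in 1:5) expect_equal(unname(p[i, ]), marg, tolerance = 1e-4)
})

test_that("CLM with one predictor matches a direct likelihood-maximisation oracle", {
  set.seed(3)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  y <- pmin(pmax(round(1 + 2 * x + rnorm(n, 0, 0.9)), 0), 4)
  d <- tibble::tibble(x = x, target = as.integer(y))
  fit <- fit_clm(d, features = "x")
  orc <- polr_oracle(x, y)
  expect_equal(unname(fit$fit$zeta), unname(orc$zeta), tolerance = 1e-4)
  expect_equal(unname(coef(fit$fit)), unname(orc$beta), tolerance = 1e-4)
})

test_that("CLM cumulative probabilities are non-decreasing and decisions differ by rule", {
  d <- sim_ordinal_table(400, seed = 5)
  fit <- fit_clm(d)
  p <- predict(fit, d, type = "prob")
  expect_true(all(abs(rowSums(p) - 1) < 1e-8))
  cum <- t(apply(p, 1, cumsum))
  expect_true(all(diff(t(cum)) >= -1e-10))
  med <- predict(fit, d, type = "class", decision = "median")
  expect_true(all(med %in% 0:4))
})

test_that("ODT learns pure structure and respects constant labels", {
  # pure split: one feature separates low from high labels
  d <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                      target = c(rep(1L, 20), rep(3L, 20)))
  tr <- fit_odt(d, prune = FALSE, min_split = 2, min_leaf = 1)
  expect_equal(predict(tr, tibble::tibble(x = c(0, 1))), c(1, 3))

  dc <- tibble::tibble(x = rnorm(50), target = rep(2L, 50))
  trc <- fit_odt(dc, prune = FALSE)
  expect_equal(n_tree_nodes(trc), 1L)
  expect_equal(unique(predict(trc, dc)), 2)
})

test_that("the ODT split equals the exhaustive absolute-error oracle in 1-D", {
  set.seed(12)
  for (i in 1:10) {
    n <- 80
    x <- round(rnorm(n), 1)
    y <- pmin(pmax(round(2 + 1.5 * (x > 0.3) + rnorm(n, 0, 0.7)), 0), 4)
    d <- tibble::tibble(x = x, target = as.integer(y))
    tr <- fit_odt(d, max_depth = 1, prune = FALSE, min_split = 2, min_leaf = 1)
    if (tr$root$leaf) next
    orc <- best_mae_split_oracle(x, y)
    # the package split must achieve the oracle's optimal cost
    thr <- tr$root$split$threshold
    cost_pkg <- sum(abs(y[x <= thr] - median_int(y[x <= thr]))) +
      sum(abs(y[x > thr] - median_int(y[x > thr])))
    expect_lte(cost_pkg, orc$cost + 1e-9)
  }
})

test_that("gain-ratio tree handles XOR, closed-form gain ratio, and pruning to the root", {
  # XOR-style interaction needs depth 2 (cells slightly unbalanced so the
  # greedy first split has positive marginal gain)
  g <- expand.grid(a = c(0, 1), b = c(0, 1))
  d <- g[rep(1:4, times = c(9, 10, 11, 12)), ]
  d$target <- as.integer(xor(d$a, d$b))
  tr <- fit_multiclass_tree(d, prune = FALSE, min_split = 2, min_leaf = 1,
                            max_depth = 3)
  expect_equal(mean(predict(tr, d) == d$target), 1)

  # perfectly separating binary feature: gain ratio = prior entropy /
  # split info = 1 when classes are balanced
  db <- tibble::tibble(x = rep(c(0, 1), each = 30),
                       target = rep(c(0L, 4L), each = 30))
  trb <- fit_multiclass_tree(db, prune = FALSE, min_split = 2, min_leaf = 1)
  expect_equal(trb$root$split$score, 1, tolerance = 1e-10)

  # independent labels: pruning collapses to (nearly) the root
  set.seed(33)
  dn <- tibble::tibble(x1 = rnorm(300), x2 = rnorm(300),
                       target = sample(0:4, 300, TRUE))
  pruned <- fit_multiclass_tree(dn, prune = TRUE, seed = 4)
  grown <- fit_multiclass_tree(dn, prune = FALSE, seed = 4)
  expect_lt(n_tree_nodes(pruned), n_tree_nodes(grown))
  expect_equal(n_tree_nodes(pruned), 1L)
})

test_that("depth-0 CPT reduces to the modal-class predictor exactly", {
  d <- sim_ordinal_table(300, seed = 7)
  cpt <- fit_cpt(d, max_depth = 0, prune = FALSE)
  pred <- predict(cpt, d)
  mode <- as.numeric(names(which.max(table(d$target))))
  expect_true(all(pred == mode))
  expect_equal(mae(pred, d$target),
               mae(rep(mode, nrow(d)), d$target))
})

test_that("CPT differencing reproduces hand-computed probabilities on a separable pair", {
  d <- tibble::tibble(x = c(rep(0, 10), rep(1, 10)),
                      target = c(rep(0L, 10), rep(4L, 10)))
  cpt <- fit_cpt(d, prune = FALSE, min_split = 2, min_leaf = 1)
  pred <- predict(cpt, tibble::tibble(x = c(0, 1)))
  expect_equal(pred, c(0, 4))
  pr <- predict(cpt, tibble::tibble(x = c(0, 1)), type = "prob")
  expect_equal(unname(pr[1, "0"]), 1)
  expect_equal(unname(pr[2, "4"]), 1)
})

test_that("seeded random forests are reproducible", {
  d <- sim_ordinal_table(200, seed = 9)
  f1 <- fit_rf(d, n_trees = 50, seed = 5)
  f2 <- fit_rf(d, n_trees = 50, seed = 5)
  expect_equal(predict(f1, d), predict(f2, d))
  f3 <- fit_rf(d, n_trees = 1, bootstrap = FALSE, seed = 5)
  expect_true(all(predict(f3, d) %in% 0:4))
})

test_that("cross-validation partitions rows and scores oracles and constants correctly", {
  d <- sim_ordinal_table(250, seed = 10)
  # a perfect oracle model reads the target off the test rows
  oracle <- list(perfect = function(train) structure(list(), class = "t_oracle"))
  assign("predict.t_oracle", function(object, newdata, ...) newdata$target,
         envir = globalenv())
  ev <- cv_evaluate(d, oracle, k = 10, seed = 3)
  expect_equal(ev$folds$mae, rep(0, 10))
  expect_equal(ev$folds$accuracy, rep(1, 10))
  cm <- ev$confusion$perfect
  expect_equal(sum(cm) , 250)
  expect_equal(sum(diag(cm)), 250)

  ev2 <- cv_evaluate(d, default_models(models = "prior"), k = 10, seed = 3)
  pooled_acc <- sum(ev2$folds$accuracy * ev2$folds$n_test) / 250
  mode_rate <- max(table(d$target)) / 250
  expect_lt(abs(pooled_acc - mode_rate), 0.05)

  # fold assignment is a partition
  folds <- alsord:::make_stratified_folds(d$target, 10, seed = 3)
  expect_equal(length(folds), 250)
  expect_true(all(folds %in% 1:10))
  expect_true(all(table(folds) > 0))
})

test_that("accuracy one forces MAE zero and confusion rows sum to class counts", {
  d <- sim_ordinal_table(200, seed = 13)
  ev <- cv_evaluate(d, default_models(models = c("odt", "prior"), seed = 2),
                    k = 5, seed = 2)
  g <- glance(ev)
  for (m in g$model) {
    sub <- ev$folds[ev$folds$model == m, ]
    if (any(sub$accuracy == 1)) {
      expect_equal(sub$mae[sub$accuracy == 1], rep(0, sum(sub$accuracy == 1)))
    }
    cm <- ev$confusion[[m]]
    expect_equal(unname(rowSums(cm)),
                 unname(as.integer(table(factor(d$target, levels = 0:4)))))
    expect_equal(sum(diag(cm)) / sum(cm),
                 sum(sub$accuracy * sub$n_test) / sum(sub$n_test),
                 tolerance = 1e-10)
  }
})

test_that("paired comparisons match the textbook t statistic and flag degeneracies", {
  a <- c(0.5, 0.6, 0.7, 0.8, 0.55, 0.65, 0.72, 0.61, 0.58, 0.69)
  b <- c(0.52, 0.64, 0.66, 0.85, 0.5, 0.7, 0.7, 0.66, 0.6, 0.72)
  out <- compare_models(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out$t, t_hand, tolerance = 1e-10)
  expect_equal(out$df, 9)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), 9), tolerance = 1e-10)

  same <- compare_models(a, a)
  expect_equal(same$note, "identical")
  shift <- compare_models(a, a + 0.1)
  expect_equal(shift$note, "identical-shift")
  expect_equal(shift$mean_diff, -0.1)
})
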