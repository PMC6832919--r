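test_that("Markov blankets follow the definition, checked against an oracle", {
  nodes <- c("X", "Class", "Y", "Z")
  edges <- tibble::tibble(from = c("X", "Class", "Z"),
                          to = c("Class", "Y", "Y"))
  expect_setequal(markov_blanket(edges, class_node = "Class"),
                  c("X", "Y", "Z"))
  expect_equal(markov_blanket(tibble::tibble(from = character(),
                                             to = character()),
                              class_node = "Class"), character(0))
  # 50 random DAGs against the adjacency-matrix recomputation
  nds <- paste0("n", 1:8)
  for (s in 1:50) {
    dag <- random_dag(nds, p = 0.3, seed = s)
    expect_setequal(markov_blanket(dag, class_node = "n3"),
                    mb_oracle(dag, nds, "n3"))
  }
})

test_that("inference on planted models matches full-joint enumeration", {
  dat <- sample_bn(planted_mb_network(), 1500, seed = 4)
  edges <- tibble::tibble(from = c("A", "B", "Class"),
                          to = c("Class", "Class", "C"))
  model <- bn_from_structure(dat, edges, "Class")
  # full evidence rows: fast path, partial-evidence path, and oracle agree
  for (i in c(1, 7, 20, 55)) {
    ev <- as.list(dat[i, c("A", "B", "C", "D")])
    post <- bn_predict(model, ev)
    orc <- bn_posterior_oracle(model, ev)
    expect_equal(post, orc, tolerance = 1e-9)
    fast <- predict(model, dat[i, ], type = "prob")
    expect_equal(unname(fast[1, ]), unname(orc), tolerance = 1e-9)
  }
  # missing evidence is marginalised exactly
  post_m <- bn_predict(model, list(A = "a1", C = "y"))
  orc_m <- bn_posterior_oracle(model, list(A = "a1", C = "y"))
  expect_equal(post_m, orc_m, tolerance = 1e-9)
  # empty evidence returns the (smoothed) prior over the class
  post0 <- bn_predict(model, list())
  orc0 <- bn_posterior_oracle(model, list())
  expect_equal(post0, orc0, tolerance = 1e-9)
})

test_that("the kept Markov blanket is sufficient for prediction", {
  dat <- sample_bn(planted_mb_network(), 1200, seed = 9)
  edges <- tibble::tibble(from = c("A", "B", "Class"),
                          to = c("Class", "Class", "C"))
  model <- bn_from_structure(dat, edges, "Class")
  mb_model <- bn_keep_mb(model, dat)
  expect_setequal(markov_blanket(model), c("A", "B", "C"))
  p_full <- predict(model, dat[1:50, ], type = "prob")
  p_mb <- predict(mb_model, dat[1:50, c("A", "B", "C", "Class")],
                  type = "prob")
  expect_equal(p_full, p_mb, tolerance = 1e-9)
})

test_that("deterministic parents dominate the posterior up to smoothing", {
  n <- list(
    bn_node("P", c("0", "1"), cpt = c(0.5, 0.5)),
    bn_node("Class", c("0", "1"), parents = "P",
            cpt = array(c(1, 0, 0, 1), dim = c(2, 2)))
  )
  dat <- sample_bn(n, 500, seed = 2)
  model <- bn_from_structure(dat, tibble::tibble(from = "P", to = "Class"),
                             "Class")
  post <- bn_predict(model, list(P = "1"))
  expect_gt(post[["1"]], 0.98)
})

test_that("structure search leaves an independent class disconnected", {
  set.seed(30)
  n <- 600
  dat <- tibble::tibble(
    a = sample(c("0", "1"), n, replace = TRUE),
    b = sample(c("x", "y", "z"), n, replace = TRUE),
    target = sample(c("0", "1", "2"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  )
  model <- rmcv_learn(dat, "target", seed = 3)
  expect_equal(length(markov_blanket(model)), 0)
  modal <- names(which.max(table(dat$target)))
  expect_true(all(predict(model, dat[1:20, ]) == modal))
  expect_lt(abs(model$score - max(table(dat$target)) / n), 0.05)
})

test_that("structure search recovers a planted blanket and respects its invariants", {
  dat <- sample_bn(planted_mb_network(), 3000, seed = 17)
  model <- rmcv_learn(dat, "Class", seed = 5)
  mb <- markov_blanket(model)
  expect_true(all(c("A", "B", "C") %in% mb))
  expect_false("D" %in% mb)
  # acyclic, score at least the empty graph's, CPT rows normalised
  expect_true(alsord:::edges_acyclic(model$edges, model$nodes))
  expect_gte(model$score, model$trace$score[1] - 1e-12)
  for (cpt in model$cpts) {
    nd <- length(dim(cpt))
    sums <- if (nd == 1) sum(cpt) else apply(cpt, seq_len(nd - 1), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("rmcv accepts only acyclic graphs and stratifies its folds", {
  dat <- sample_bn(planted_mb_network(), 800, seed = 21)
  model <- rmcv_learn(dat, "Class", max_parents = 2, seed = 7)
  expect_true(all(table(model$edges$to) <= 2 + 1))  # max_parents bound
  expect_true(alsord:::edges_acyclic(model$edges, model$nodes))
  expect_error(bn_from_structure(dat, tibble::tibble(from = c("A", "Class"),
                                                     to = c("Class", "A")),
                                 "Class"),
               class = "alsord_config_error")
})
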