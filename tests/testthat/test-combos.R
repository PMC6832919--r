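test_that("severity split follows the severe/mild definitions", {
  d <- tibble::tibble(patient_id = paste0("P", 1:5), target = 0:4)
  g <- split_severity(d)
  expect_setequal(g$severe, c("P1", "P2"))
  expect_setequal(g$mild, c("P4", "P5"))
  expect_equal(g$excluded, "P3")

  d4 <- tibble::tibble(patient_id = paste0("P", 1:4), target = rep(4, 4))
  expect_warning(g4 <- split_severity(d4), "empty")
  expect_equal(length(g4$severe), 0)

  set.seed(40)
  d20 <- tibble::tibble(patient_id = paste0("P", 1:20),
                        target = sample(0:4, 20, replace = TRUE))
  g20 <- split_severity(d20)
  expect_equal(length(g20$severe), sum(d20$target <= 1))
  expect_equal(length(g20$mild), sum(d20$target >= 3))
  expect_equal(length(c(g20$severe, g20$mild, g20$excluded)), 20)
})

test_that("the four analysis variables are the top-importance blanket members", {
  imp <- structure(tibble::tibble(
    predictor = c("fvc_percent_last", "lab_alt_last", "lab_chloride_last",
                  "onset_site", "lab_ck_last", "age"),
    si = c(0.3, 0.25, 0.2, 0.15, 0.07, 0.03),
    vli = c(0.3, 0.25, 0.2, 0.15, 0.07, 0.03),
    rank = 1:6), class = c("als_importance", "tbl_df", "tbl", "data.frame"))
  mb <- c("lab_ck_last", "onset_site", "lab_alt_last", "age",
          "fvc_percent_last", "lab_chloride_last")
  four <- select_four_variables(mb, imp)
  expect_setequal(four, c("fvc_percent_last", "lab_alt_last",
                          "lab_chloride_last", "onset_site"))
  expect_warning(
    short <- select_four_variables(c("age", "onset_site", "lab_ck_last"), imp),
    "fewer than four")
  expect_equal(length(short), 3)
  expect_true(attr(short, "short_set"))
})

test_that("combination frequencies equal direct counts and sum to 100 per group", {
  d <- tibble::tibble(
    patient_id = paste0("P", 1:10),
    a = c("l", "l", "h", "h", "l", "h", "l", "l", "h", "h"),
    b = c("x", "y", "x", "y", "x", "x", "y", "x", "y", "x"),
    target = c(0, 1, 0, 1, 4, 3, 4, 3, 4, 2)
  )
  g <- split_severity(d)
  ct <- combination_frequencies(d, c("a", "b"), g, top_k = 2)
  expect_equal(nrow(ct), 4)
  expect_equal(sum(ct$severe_pct), 100, tolerance = 1e-6)
  expect_equal(sum(ct$mild_pct), 100, tolerance = 1e-6)
  # direct tally: severe patients P1..P4 have combos lx, ly, hx, hy
  expect_equal(ct$severe_pct[ct$a == "l" & ct$b == "x"], 25)
  # mild patients P5..P9: lx, hx, ly(P7 b=y -> "ly"), lx(P8 b=x a=l -> lx)...
  mild_rows <- d[d$target >= 3, ]
  key <- paste(mild_rows$a, mild_rows$b)
  for (i in seq_len(nrow(ct))) {
    expect_equal(ct$mild_pct[i],
                 100 * sum(key == paste(ct$a[i], ct$b[i])) / nrow(mild_rows))
  }
  # single patient per group puts 100% on its combination
  d1 <- tibble::tibble(patient_id = c("A", "B"), a = c("l", "h"),
                       b = c("x", "y"), target = c(0, 4))
  ct1 <- combination_frequencies(d1, c("a", "b"), split_severity(d1))
  expect_equal(max(ct1$severe_pct), 100)
  expect_equal(max(ct1$mild_pct), 100)
})

test_that("frequencies are invariant to row order and missing values are excluded", {
  set.seed(41)
  d <- tibble::tibble(
    patient_id = paste0("P", 1:40),
    a = sample(c("l", "h"), 40, TRUE),
    b = sample(c("x", "y"), 40, TRUE),
    target = sample(c(0, 1, 3, 4), 40, TRUE)
  )
  g <- split_severity(d)
  c1 <- combination_frequencies(d, c("a", "b"), g)
  c2 <- combination_frequencies(d[sample(40), ], c("a", "b"), g)
  expect_equal(as.data.frame(c1), as.data.frame(c2))

  d$a[1] <- NA
  expect_warning(c3 <- combination_frequencies(d, c("a", "b"), g),
                 "excluded")
  expect_equal(sum(c3$severe_pct), 100, tolerance = 1e-6)
})

test_that("FVC quartile levels use the four canonical labels", {
  set.seed(42)
  v <- rnorm(200, 70, 15)
  lv <- fvc_quartile_levels(v)
  expect_setequal(unique(lv), c("low", "moderate_low", "moderate_high", "high"))
  expect_equal(as.numeric(table(lv)), rep(50, 4))
  # low levels correspond to low values
  expect_lt(max(v[lv == "low"]), min(v[lv == "high"]))
})

test_that("a strongly enriched severe combination ranks first", {
  set.seed(43)
  hits <- 0
  for (s in 1:10) {
    n_sev <- 80; n_mild <- 80
    sev <- tibble::tibble(
      patient_id = paste0("S", 1:n_sev),
      a = sample(c("l", "h"), n_sev, TRUE, prob = c(0.85, 0.15)),
      b = sample(c("x", "y"), n_sev, TRUE, prob = c(0.85, 0.15)),
      target = sample(0:1, n_sev, TRUE)
    )
    mild <- tibble::tibble(
      patient_id = paste0("M", 1:n_mild),
      a = sample(c("l", "h"), n_mild, TRUE),
      b = sample(c("x", "y"), n_mild, TRUE),
      target = sample(3:4, n_mild, TRUE)
    )
    d <- dplyr::bind_rows(sev, mild)
    ct <- combination_frequencies(d, c("a", "b"), split_severity(d))
    top <- ct[ct$severe_rank == 1, ]
    if (top$a == "l" && top$b == "x") hits <- hits + 1
  }
  expect_gte(hits, 9)
})
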