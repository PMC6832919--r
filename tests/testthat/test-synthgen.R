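test_that("zero-patient cohort yields empty tables with the full schemas", {
  co <- simulate_cohort(0, seed = 1)
  expect_named(co$tables, c("demographics", "alshx", "riluzole", "alsfrs",
                            "fvc", "labs", "vitals"))
  for (tab in co$tables) expect_equal(nrow(tab), 0)
  expect_true(all(alsfrs_items() %in% names(co$tables$alsfrs)))
  expect_true(all(c("patient_id", "visit_day", "variable", "value") %in%
                    names(co$tables$labs)))
})

test_that("identical config and seed reproduce byte-identical tables", {
  a <- simulate_cohort(60, seed = 7, emit_revised = 0.3)
  b <- simulate_cohort(60, seed = 7, emit_revised = 0.3)
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth$severity, b$truth$severity)
  c <- simulate_cohort(60, seed = 8, emit_revised = 0.3)
  expect_false(identical(a$tables$labs, c$tables$labs))
})

test_that("generated ALSFRS values are integers in 0..4 and deterioration is monotone", {
  co <- simulate_cohort(150, seed = 3)
  af <- co$tables$alsfrs
  vals <- unlist(af[alsfrs_items()])
  vals <- vals[!is.na(vals)]
  expect_true(all(vals %in% 0:4))
  # latent severity never decreases over visits
  sev <- co$truth$severity
  by_pg <- split(sev, paste(sev$patient_id, sev$group))
  ok <- vapply(by_pg, function(d) {
    d <- d[order(d$visit_day), ]
    all(diff(d$severity) >= 0)
  }, logical(1))
  expect_true(all(ok))
  # last-visit ALSFRS values are never missing
  last_rows <- do.call(rbind, lapply(split(af, af$patient_id), function(d) {
    d[which.max(d$visit_day), ]
  }))
  expect_false(anyNA(last_rows[setdiff(alsfrs_items(), "respiratory")]))
})

test_that("first-to-last intervals match the configured distribution", {
  co <- simulate_cohort(600, seed = 11)
  # fvc has one row per scheduled visit, so it carries the full schedule
  af <- co$tables$fvc
  iv <- vapply(split(af$visit_day, af$patient_id),
               function(d) max(d) - min(d), numeric(1))
  expect_true(all(iv > 0))
  se <- 167.5 / sqrt(length(iv))
  expect_lt(abs(mean(iv) - 333.8), 3 * se)
})

test_that("link strengths induce rank correlations of the implied sign", {
  co <- simulate_cohort(cohort_config(2000, seed = 5, missing_rate = 0,
                                      sparse_labs = character(0)))
  ds <- build_patient_dataset(co)
  d <- ds$data
  # positive strength: lab rises with severity, so falls with the item value
  r_ck <- cor(d$lab_ck_last, d$alsfrs_swallowing_last, method = "spearman")
  expect_lt(r_ck, -0.1)
  # negative strength: lab falls with severity, rises with the item value
  r_cr <- cor(d$lab_creatinine_last, d$alsfrs_walking_last, method = "spearman")
  expect_gt(r_cr, 0.1)
  r_cl <- cor(d$lab_chloride_last, d$alsfrs_respiratory_last, method = "spearman")
  expect_gt(r_cl, 0.1)
})

test_that("with all link strengths zero every lab has vanishing sensitivity", {
  lm0 <- default_link_matrix()
  lm0$strength <- 0
  co <- simulate_cohort(cohort_config(1500, seed = 9, group_link_matrix = lm0,
                                      missing_rate = 0,
                                      sparse_labs = character(0)))
  ds <- build_patient_dataset(co)
  mt <- assemble_setting(ds, "last", "walking")
  labs <- grep("^lab_", table_features(mt), value = TRUE)
  si <- vapply(labs, function(l) sensitivity(mt, l), numeric(1))
  expect_true(all(si < 0.03))
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohort_config(-1), class = "alsord_config_error")
  expect_error(cohort_config(10, missing_rate = 1), class = "alsord_config_error")
  expect_error(cohort_config(10, onset_site_probs = c(bulbar = 0.7, limb = 0.7)),
               class = "alsord_config_error")
})

test_that("ancestral sampling honours deterministic and stochastic CPTs", {
  # single certain root
  n1 <- list(bn_node("A", c("0", "1"), cpt = c(0, 1)))
  expect_true(all(sample_bn(n1, 50, seed = 1)$A == "1"))
  # deterministic chain copies the parent
  n2 <- list(
    bn_node("A", c("0", "1"), cpt = c(0.5, 0.5)),
    bn_node("B", c("0", "1"), parents = "A",
            cpt = array(c(1, 0, 0, 1), dim = c(2, 2)))
  )
  d2 <- sample_bn(n2, 100, seed = 2)
  expect_identical(d2$A, d2$B)
  # v-structure: empirical conditionals approach the specification
  cpt <- array(c(0.9, 0.6, 0.3, 0.1,
                 0.1, 0.4, 0.7, 0.9), dim = c(2, 2, 2))
  n3 <- list(
    bn_node("A", c("0", "1"), cpt = c(0.5, 0.5)),
    bn_node("B", c("0", "1"), cpt = c(0.5, 0.5)),
    bn_node("C", c("0", "1"), parents = c("A", "B"), cpt = cpt)
  )
  d3 <- sample_bn(n3, 5000, seed = 3)
  for (a in 1:2) for (b in 1:2) {
    sel <- d3$A == c("0", "1")[a] & d3$B == c("0", "1")[b]
    expect_lt(abs(mean(d3$C[sel] == "1") - cpt[a, b, 2]), 0.03)
  }
  # cyclic specifications are rejected
  cyc <- list(
    bn_node("A", c("0", "1"), parents = "B",
            cpt = array(c(0.5, 0.5, 0.5, 0.5), dim = c(2, 2))),
    bn_node("B", c("0", "1"), parents = "A",
            cpt = array(c(0.5, 0.5, 0.5, 0.5), dim = c(2, 2)))
  )
  expect_error(sample_bn(cyc, 10, seed = 1), class = "alsord_config_error")
})
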