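make_raw_tables <- function(patients) {
  # patients: list of lists with id, visits (tibble visit_day + items),
  # optionally labs (long tibble)
  items <- alsfrs_items()
  af <- dplyr::bind_rows(lapply(patients, function(p) {
    dplyr::bind_cols(tibble::tibble(patient_id = p$id), p$visits)
  }))
  for (it in items) if (!it %in% names(af)) af[[it]] <- 4L
  ids <- vapply(patients, `[[`, "", "id")
  labs <- dplyr::bind_rows(lapply(patients, function(p) {
    p$labs %||% tibble::tibble(patient_id = character(), visit_day = integer(),
                               variable = character(), value = double())
  }))
  list(
    demographics = tibble::tibble(patient_id = ids, age = 60, gender = "M"),
    alshx = tibble::tibble(patient_id = ids, onset_site = "limb",
                           onset_delta = -300),
    riluzole = tibble::tibble(patient_id = ids, riluzole = 1L),
    alsfrs = af,
    fvc = tibble::tibble(patient_id = rep(ids, each = 2),
                         visit_day = rep(c(0L, 100L), length(ids)),
                         fvc_liters = 3, fvc_normal = 4),
    labs = labs,
    vitals = tibble::tibble(patient_id = character(), visit_day = integer(),
                            variable = character(), value = double())
  )
}

two_visits <- function(speech = c(4L, 3L)) {
  tibble::tibble(visit_day = c(0L, 100L), speech = speech)
}

test_that("revised respiratory records collapse to the Dyspnea value", {
  expect_equal(collapse_respiratory(3L, 4L, 4L), 3L)
  expect_equal(collapse_respiratory(4L, 4L, 4L), 4L)
  expect_equal(collapse_respiratory(0L, 2L, 3L), 0L)
  expect_equal(collapse_respiratory(c(1L, 2L), c(0L, 0L), c(4L, 4L)),
               c(1L, 2L))
  expect_error(collapse_respiratory(5L, 0L, 0L), class = "alsord_config_error")
})

test_that("FVC percent-of-normal conversion is exact and never imputes", {
  expect_equal(fvc_to_percent(3.0, 4.0), 75.0)
  expect_equal(fvc_to_percent(4.0, 4.0), 100.0)
  expect_equal(fvc_to_percent(2.2, 4.4), 50.0)
  expect_true(is.na(fvc_to_percent(3.0, 0)))
  expect_true(is.na(fvc_to_percent(3.0, NA)))
})

test_that("patients without two documented ALSFRS visits are dropped with reasons", {
  tabs <- make_raw_tables(list(
    list(id = "P1", visits = two_visits()),
    list(id = "P2", visits = tibble::tibble(visit_day = c(0L, 100L),
                                            speech = c(NA_integer_, NA_integer_))),
    list(id = "P3", visits = two_visits(c(2L, 2L)))
  ))
  ds <- build_patient_dataset(tabs)
  expect_setequal(ds$data$patient_id, c("P1", "P3"))
  expect_equal(ds$log$dropped_patients$reason[
    ds$log$dropped_patients$patient_id == "P2"], "no documented ALSFRS")

  tabs1 <- make_raw_tables(list(
    list(id = "P1", visits = two_visits()),
    list(id = "P4", visits = tibble::tibble(visit_day = 0L, speech = 4L))
  ))
  ds1 <- build_patient_dataset(tabs1)
  expect_false("P4" %in% ds1$data$patient_id)
  expect_equal(ds1$log$dropped_patients$reason[
    ds1$log$dropped_patients$patient_id == "P4"],
    "fewer than two ALSFRS visits")
})

test_that("sparse variables are dropped by the threshold instead of their patients", {
  mk_lab <- function(id, with_x) {
    base <- tibble::tibble(patient_id = id, visit_day = c(0L, 100L),
                           variable = "ok", value = 1)
    if (with_x) {
      base <- dplyr::bind_rows(base, tibble::tibble(
        patient_id = id, visit_day = c(0L, 100L), variable = "x", value = 2))
    }
    base
  }
  patients <- lapply(1:10, function(i) {
    list(id = sprintf("P%02d", i), visits = two_visits(),
         labs = mk_lab(sprintf("P%02d", i), with_x = i <= 4))
  })
  ds <- build_patient_dataset(make_raw_tables(patients), drop_threshold = 0.4)
  expect_true(all(c("lab_x_first", "lab_x_last") %in%
                    ds$log$dropped_variables$column))
  expect_equal(nrow(ds$data), 10)  # nobody dropped on account of x
  expect_false("lab_x_last" %in% names(ds$data))
})

test_that("first and last visits are the extreme documented ALSFRS days", {
  tabs <- make_raw_tables(list(
    list(id = "P1",
         visits = tibble::tibble(visit_day = c(0L, 90L, 400L),
                                 speech = c(4L, 3L, 1L)))
  ))
  ds <- build_patient_dataset(tabs)
  expect_equal(ds$data$time_var, 400)
  expect_equal(ds$data$alsfrs_speech_first, 4L)
  expect_equal(ds$data$alsfrs_speech_last, 1L)
})

test_that("setting tables carry exactly the specified feature blocks", {
  co <- simulate_cohort(120, seed = 2)
  ds <- build_patient_dataset(co)
  for (s in c("last", "both", "first")) {
    mt <- assemble_setting(ds, s, "speech")
    f <- table_features(mt)
    expect_false(any(grepl("^alsfrs_", f)))     # no ALSFRS item is a feature
    if (s == "last") {
      expect_false(any(grepl("_first$", f)))
      expect_false("time_var" %in% f)
    }
    if (s == "first") {
      expect_false(any(grepl("_last$", f)))
      expect_true("time_var" %in% f)
    }
    if (s == "both") {
      expect_true(any(grepl("_first$", f)) && any(grepl("_last$", f)))
      expect_true("time_var" %in% f)
    }
    expect_equal(nrow(mt), nrow(ds$data))
    expect_true(all(mt$target %in% 0:4))
  }
  # row count identical across the ten items
  counts <- vapply(alsfrs_items(), function(it) {
    nrow(assemble_setting(ds, "last", it))
  }, numeric(1))
  expect_equal(unname(unique(counts)), nrow(ds$data))
  expect_error(assemble_setting(ds, "last", "grip"),
               class = "alsord_config_error")
})

test_that("preparation is idempotent on its own survivors", {
  co <- simulate_cohort(150, seed = 6)
  ds <- build_patient_dataset(co)
  keep <- ds$data$patient_id
  kept_vars <- setdiff(unique(sub("^(lab_|vital_)", "",
                                  sub("_(first|last)$", "",
                                      ds$log$dropped_variables$column))), "")
  tabs2 <- lapply(co$tables, function(t) t[t$patient_id %in% keep, ])
  tabs2$labs <- tabs2$labs[!tabs2$labs$variable %in% kept_vars, ]
  ds2 <- build_patient_dataset(tabs2)
  expect_equal(nrow(ds2$data), nrow(ds$data))
  common <- intersect(names(ds$data), names(ds2$data))
  expect_equal(as.data.frame(ds2$data[common]),
               as.data.frame(ds$data[common]))
})
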