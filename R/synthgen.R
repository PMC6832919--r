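# Synthetic PRO-ACT-like cohort generator.
#
# The generator emulates the statistical shape of pooled ALS clinical-trial
# visit tables: ~25 laboratory variables, vitals, FVC, static variables
# (onset site, gender, age, onset time), and the ten ordinal ALSFRS items
# at a first and a last clinic visit.  Each patient carries a latent
# per-functional-group severity that declines linearly in time with a
# patient-specific random slope; ALSFRS items are produced by rounding and
# clipping (4 - severity + noise) to {0..4}; laboratory variables are tied
# monotonically to the severity of their functional group through a
# configurable link matrix, giving every downstream stage a known ground
# truth.

#' Default lab-to-functional-group link matrix
#'
#' One row per laboratory variable giving its reference mean and standard
#' deviation (synthetic but clinically plausible units) and its link to one
#' of the five ALSFRS functional groups.  `strength` is the coefficient of
#' standardized group severity in the lab's standardized value: positive
#' means the lab rises as function deteriorates, negative that it falls,
#' zero that the lab is pure noise.
#'
#' @return A tibble with columns `lab`, `group`, `strength`, `mean`, `sd`.
#' @export
default_link_matrix <- function() {
  tribble_env <- tibble::tribble(
    ~lab,                   ~group,        ~strength, ~mean,  ~sd,
    "ck",                   "bulbar",       0.8,      180,    90,
    "phosphorus",           "upper_limb",   0.8,      3.5,    0.5,
    "creatinine",           "lower_limb",  -0.8,      0.9,    0.2,
    "ast",                  "full_body",    0.8,      26,     9,
    "chloride",             "respiratory", -0.8,      102,    3,
    "alkaline_phosphatase", "lower_limb",   0.4,      78,     22,
    "alt",                  "full_body",    0.3,      28,     11,
    "glucose",              "bulbar",      -0.3,      95,     14,
    "hemoglobin",           "respiratory", -0.3,      14.2,   1.3,
    "albumin",              "full_body",   -0.3,      4.3,    0.3,
    "calcium",              NA,             0,        9.4,    0.4,
    "sodium",               NA,             0,        140,    2.5,
    "potassium",            NA,             0,        4.2,    0.35,
    "bicarbonate",          NA,             0,        25,     2.4,
    "bilirubin_total",      NA,             0,        0.6,    0.25,
    "protein_total",        NA,             0,        7.0,    0.45,
    "hematocrit",           NA,             0,        42,     3.8,
    "platelets",            NA,             0,        250,    55,
    "wbc",                  NA,             0,        7.0,    1.8,
    "rbc",                  NA,             0,        4.7,    0.45,
    "urea_nitrogen",        NA,             0,        15,     4.5,
    "uric_acid",            NA,             0,        5.2,    1.2,
    "triglycerides",        NA,             0,        130,    55,
    "cholesterol",          NA,             0,        195,    35,
    "ggt",                  NA,             0,        30,     16
  )
  tribble_env
}

#' Configure the synthetic cohort generator
#'
#' @param n_patients Number of patients to simulate (>= 0).
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   tables.
#' @param interval_mean,interval_sd Mean and SD (days) of the first-to-last
#'   visit interval, drawn from a normal truncated to be strictly positive.
#'   Defaults 333.8 and 167.5 days.
#' @param group_link_matrix Lab-to-group link matrix as returned by
#'   [default_link_matrix()].
#' @param missing_rate Per-value completely-at-random missingness fraction
#'   in `[0, 1)`.  Never applied to patient identifiers or to the
#'   last-visit ALSFRS values.  Kept low by default because the prepared
#'   dataset is complete-case: pooled-trial data are mostly complete for
#'   routine panels, with sparsity concentrated in a few variables
#'   (`sparse_labs`).
#' @param sparse_labs Labs recorded with high missingness (`sparse_rate`),
#'   emulating assays absent from most trial protocols; these exercise the
#'   variable-drop rule of the preparation stage.
#' @param sparse_rate Missingness fraction for `sparse_labs`.
#' @param onset_site_probs Named probabilities over `c(bulbar, limb)`.
#' @param progression_rate_sd SD of the patient-specific decline slope
#'   (severity points per year).
#' @param progression_rate_mean Mean decline slope (points per year).
#' @param item_noise_sd SD of the per-item observation noise added to the
#'   latent severity before rounding.
#' @param emit_revised Fraction of patients whose respiratory function is
#'   recorded on the revised three-item scale (Dyspnea, Orthopnea,
#'   Respiratory insufficiency) instead of the single respiratory item.
#' @param extra_visit_rate Poisson rate of additional visits between the
#'   first and last one.
#'
#' @return A list of class `als_cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          seed = 1L,
                          interval_mean = 333.8,
                          interval_sd = 167.5,
                          group_link_matrix = default_link_matrix(),
                          missing_rate = 0.005,
                          sparse_labs = c("triglycerides", "ggt"),
                          sparse_rate = 0.6,
                          onset_site_probs = c(bulbar = 0.25, limb = 0.75),
                          progression_rate_sd = 0.6,
                          progression_rate_mean = 1.3,
                          item_noise_sd = 0.55,
                          emit_revised = 0,
                          extra_visit_rate = 0.7) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 0) {
    abort_config("n_patients must be a single non-negative number")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort_config("missing_rate must lie in [0, 1)")
  }
  if (any(onset_site_probs < 0) || any(onset_site_probs > 1) ||
      abs(sum(onset_site_probs) - 1) > 1e-8) {
    abort_config("onset_site_probs must be probabilities summing to 1")
  }
  if (!all(c("bulbar", "limb") %in% names(onset_site_probs))) {
    abort_config("onset_site_probs must be named over bulbar and limb")
  }
  if (interval_mean <= 0 || interval_sd < 0) {
    abort_config("interval parameters must be positive")
  }
  req <- c("lab", "group", "strength", "mean", "sd")
  if (!all(req %in% names(group_link_matrix))) {
    abort_config("group_link_matrix needs columns lab, group, strength, mean, sd")
  }
  bad_grp <- setdiff(stats::na.omit(group_link_matrix$group), names(alsfrs_groups()))
  if (length(bad_grp) > 0) {
    abort_config(paste("unknown functional group(s):", paste(bad_grp, collapse = ", ")))
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      interval_mean = interval_mean, interval_sd = interval_sd,
      group_link_matrix = group_link_matrix, missing_rate = missing_rate,
      sparse_labs = sparse_labs, sparse_rate = sparse_rate,
      onset_site_probs = onset_site_probs,
      progression_rate_sd = progression_rate_sd,
      progression_rate_mean = progression_rate_mean,
      item_noise_sd = item_noise_sd, emit_revised = emit_revised,
      extra_visit_rate = extra_visit_rate
    ),
    class = "als_cohort_config"
  )
}

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# normal truncated to strictly positive values, by rejection
rnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

empty_cohort_tables <- function() {
  items <- alsfrs_items()
  alsfrs_cols <- c(
    stats::setNames(rep("integer", 10), items),
    r1_dyspnea = "integer", r2_orthopnea = "integer",
    r3_resp_insuff = "integer", scale = "character"
  )
  make <- function(cols) {
    tibble::as_tibble(lapply(cols, function(ty) vector(ty, 0)))
  }
  list(
    demographics = make(c(patient_id = "character", age = "double",
                          gender = "character")),
    alshx = make(c(patient_id = "character", onset_site = "character",
                   onset_delta = "double")),
    riluzole = make(c(patient_id = "character", riluzole = "integer")),
    alsfrs = make(c(c(patient_id = "character", visit_day = "integer"),
                    alsfrs_cols)),
    fvc = make(c(patient_id = "character", visit_day = "integer",
                 fvc_liters = "double", fvc_normal = "double")),
    labs = make(c(patient_id = "character", visit_day = "integer",
                  variable = "character", value = "double")),
    vitals = make(c(patient_id = "character", visit_day = "integer",
                    variable = "character", value = "double"))
  )
}

#' Simulate a PRO-ACT-like cohort
#'
#' Draws a cohort from the latent linear-decline model described in the
#' package vignette and returns both the raw visit tables (in the shapes the
#' preparation stage expects) and the generating ground truth.
#'
#' @param config An [cohort_config()] object, or a patient count (in which
#'   case remaining arguments are passed to [cohort_config()]).
#' @param ... Passed to [cohort_config()] when `config` is a count.
#'
#' @return A list of class `als_cohort` with elements
#'   \describe{
#'     \item{tables}{named list of tibbles: `demographics`, `alshx`,
#'       `riluzole`, `alsfrs`, `fvc`, `labs`, `vitals`.}
#'     \item{truth}{ground truth: `severity` (long tibble of latent group
#'       severities per visit), `informative_labs` (per-item character
#'       vectors of linked labs), `slopes`, and the link matrix used.}
#'     \item{config}{the configuration.}
#'   }
#' @export
simulate_cohort <- function(config, ...) {
  if (!inherits(config, "als_cohort_config")) {
    config <- cohort_config(config, ...)
  }
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  groups <- alsfrs_groups()
  gmap <- item_group_map()
  links <- cfg$group_link_matrix

  informative <- lapply(gmap, function(g) {
    links$lab[!is.na(links$group) & links$group == g & links$strength != 0]
  })

  if (n == 0) {
    return(structure(
      list(tables = empty_cohort_tables(),
           truth = list(
             severity = tibble::tibble(patient_id = character(),
                                       visit_day = integer(),
                                       group = character(),
                                       severity = double()),
             informative_labs = informative,
             slopes = tibble::tibble(patient_id = character(), slope = double()),
             link_matrix = links),
           config = cfg),
      class = "als_cohort"
    ))
  }

  pid <- sprintf("P%05d", seq_len(n))
  gender <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.4, 0.6))
  age <- round(rnorm(n, 58, 11))
  onset_site <- sample(names(cfg$onset_site_probs), n, replace = TRUE,
                       prob = cfg$onset_site_probs)
  onset_delta <- -round(rnorm_pos(n, 500, 250))
  riluzole <- rbinom(n, 1, 0.7)

  slope <- pmax(rnorm(n, cfg$progression_rate_mean, cfg$progression_rate_sd), 0.05)
  interval <- round(rnorm_pos(n, cfg$interval_mean, cfg$interval_sd))

  # visit schedule: first at day 0, last at day interval, Poisson extras between
  n_extra <- rpois(n, cfg$extra_visit_rate)
  visits <- purrr::map(seq_len(n), function(i) {
    mid <- if (n_extra[i] > 0 && interval[i] > 2) {
      sort(sample(seq_len(interval[i] - 1), min(n_extra[i], interval[i] - 1)))
    } else integer(0)
    c(0L, as.integer(mid), as.integer(interval[i]))
  })
  vtab <- tibble::tibble(
    patient_id = rep(pid, lengths(visits)),
    pidx = rep(seq_len(n), lengths(visits)),
    visit_day = unlist(visits)
  )
  m <- nrow(vtab)

  # latent severity per functional group: baseline + slope * years,
  # onset site shifting the affected groups' baselines
  gnames <- names(groups)
  base <- matrix(pmax(rnorm(n * length(gnames), 0.6, 0.35), 0),
                 nrow = n, dimnames = list(NULL, gnames))
  base[, "bulbar"] <- base[, "bulbar"] + 1.1 * (onset_site == "bulbar")
  base[, "upper_limb"] <- base[, "upper_limb"] + 0.5 * (onset_site == "limb")
  base[, "lower_limb"] <- base[, "lower_limb"] + 1.0 * (onset_site == "limb")
  years <- vtab$visit_day / 365
  sev <- base[vtab$pidx, , drop = FALSE] + slope[vtab$pidx] * years
  sev_long <- tibble::tibble(
    patient_id = rep(vtab$patient_id, times = length(gnames)),
    visit_day = rep(vtab$visit_day, times = length(gnames)),
    group = rep(gnames, each = m),
    severity = as.vector(sev)
  )

  # ALSFRS items: 4 - severity + noise, rounded, clipped to {0..4}
  items <- alsfrs_items()
  item_vals <- sapply(items, function(it) {
    s <- sev[, gmap[[it]]]
    as.integer(pmin(pmax(round(4 - s + rnorm(m, 0, cfg$item_noise_sd)), 0), 4))
  })
  revised <- runif(n) < cfg$emit_revised
  alsfrs <- tibble::as_tibble(item_vals)
  alsfrs <- dplyr::bind_cols(
    tibble::tibble(patient_id = vtab$patient_id, visit_day = vtab$visit_day),
    alsfrs
  )
  alsfrs$scale <- ifelse(revised[vtab$pidx], "ALSFRS-R", "ALSFRS")
  # revised-scale patients: respiratory reported as three items, Dyspnea
  # carrying the latent signal
  resp <- alsfrs$respiratory
  is_rev <- alsfrs$scale == "ALSFRS-R"
  alsfrs$r1_dyspnea <- ifelse(is_rev, resp, NA_integer_)
  alsfrs$r2_orthopnea <- ifelse(
    is_rev, pmin(pmax(resp + sample(c(0L, 1L), m, TRUE, c(0.7, 0.3)), 0L), 4L),
    NA_integer_)
  alsfrs$r3_resp_insuff <- ifelse(
    is_rev, pmin(pmax(resp + sample(c(0L, 1L), m, TRUE, c(0.6, 0.4)), 0L), 4L),
    NA_integer_)
  alsfrs$respiratory[is_rev] <- NA_integer_

  # FVC: percent of normal falls with respiratory severity; stored as
  # absolute litres plus the patient's normal value
  fvc_normal <- round(ifelse(gender == "M", rnorm(n, 4.4, 0.5),
                             rnorm(n, 3.4, 0.4)), 2)
  fvc_pct <- pmin(pmax(100 - 13 * sev[, "respiratory"] + rnorm(m, 0, 7), 15), 125)
  fvc <- tibble::tibble(
    patient_id = vtab$patient_id, visit_day = vtab$visit_day,
    fvc_liters = round(fvc_pct / 100 * fvc_normal[vtab$pidx], 2),
    fvc_normal = fvc_normal[vtab$pidx]
  )

  # labs: standardized value = strength * centred group severity + N(0,1)
  sev_centred <- sev - 1.5
  lab_blocks <- purrr::pmap(links, function(lab, group, strength, mean, sd) {
    z <- rnorm(m)
    if (!is.na(group) && strength != 0) {
      z <- z + strength * sev_centred[, group]
    }
    tibble::tibble(patient_id = vtab$patient_id, visit_day = vtab$visit_day,
                   variable = lab, value = round(mean + sd * z, 3))
  })
  labs <- dplyr::bind_rows(lab_blocks)

  sev_mean <- rowMeans(sev)
  weight0 <- rnorm(n, 76, 12)
  vitals <- dplyr::bind_rows(
    tibble::tibble(patient_id = vtab$patient_id, visit_day = vtab$visit_day,
                   variable = "pulse", value = round(rnorm(m, 75, 8), 1)),
    tibble::tibble(patient_id = vtab$patient_id, visit_day = vtab$visit_day,
                   variable = "bp_systolic", value = round(rnorm(m, 126, 12), 0)),
    tibble::tibble(patient_id = vtab$patient_id, visit_day = vtab$visit_day,
                   variable = "bp_diastolic", value = round(rnorm(m, 79, 8), 0)),
    tibble::tibble(patient_id = vtab$patient_id, visit_day = vtab$visit_day,
                   variable = "weight",
                   value = round(weight0[vtab$pidx] - 2.2 * sev_mean +
                                   rnorm(m, 0, 1.5), 1))
  )

  # MCAR missingness: long tables lose rows; FVC loses the absolute value;
  # non-last-visit ALSFRS rows may be absent entirely.  The last visit's
  # ALSFRS values are never removed.
  if (cfg$missing_rate > 0 || length(cfg$sparse_labs) > 0) {
    lab_rate <- ifelse(labs$variable %in% cfg$sparse_labs,
                       cfg$sparse_rate, cfg$missing_rate)
    labs <- labs[runif(nrow(labs)) >= lab_rate, ]
    vitals <- vitals[runif(nrow(vitals)) >= cfg$missing_rate, ]
    fvc$fvc_liters[runif(nrow(fvc)) < cfg$missing_rate] <- NA_real_
    last_day <- stats::ave(alsfrs$visit_day, alsfrs$patient_id,
                           FUN = max)
    droppable <- alsfrs$visit_day < last_day
    alsfrs <- alsfrs[!(droppable & runif(nrow(alsfrs)) < cfg$missing_rate), ]
  }

  structure(
    list(
      tables = list(
        demographics = tibble::tibble(patient_id = pid, age = age,
                                      gender = gender),
        alshx = tibble::tibble(patient_id = pid, onset_site = onset_site,
                               onset_delta = onset_delta),
        riluzole = tibble::tibble(patient_id = pid,
                                  riluzole = as.integer(riluzole)),
        alsfrs = alsfrs, fvc = fvc, labs = labs, vitals = vitals
      ),
      truth = list(
        severity = sev_long,
        informative_labs = informative,
        slopes = tibble::tibble(patient_id = pid, slope = slope),
        link_matrix = links
      ),
      config = cfg
    ),
    class = "als_cohort"
  )
}

#' @export
print.als_cohort <- function(x, ...) {
  cat("<als_cohort> ", x$config$n_patients, " patients, seed ",
      x$config$seed, "\n", sep = "")
  cat("tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Write the cohort tables and ground truth to disk
#'
#' One CSV per visit table plus a JSON ground-truth file, mirroring the
#' layout of a pooled-trial database export.
#'
#' @param cohort An `als_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "als_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(cohort$tables, function(tab, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE, na = "")
    p
  })
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(informative_labs = cohort$truth$informative_labs,
         slopes = cohort$truth$slopes,
         link_matrix = cohort$truth$link_matrix),
    truth_path, dataframe = "columns", digits = NA
  )
  invisible(c(paths, ground_truth = truth_path))
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory holding the CSV tables.
#' @return A named list of tibbles shaped like `als_cohort$tables`.
#' @export
read_cohort_tables <- function(dir) {
  names <- c("demographics", "alshx", "riluzole", "alsfrs", "fvc",
             "labs", "vitals")
  out <- lapply(names, function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) abort_config(paste("missing table:", p))
    tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
  })
  stats::setNames(out, names)
}
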