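# Data preparation: raw visit tables -> uniform first/last-visit dataset
# -> per-setting modelling tables.
#
# The uniform dataset holds, per surviving patient, the static variables,
# a first-visit and a last-visit snapshot of every temporal variable
# (suffixes `_first` / `_last`), the ten ALSFRS items at both endpoints,
# and `time_var`, the number of days between the two visits.

#' Collapse revised respiratory items to a single value
#'
#' The revised rating scale splits respiratory function into Dyspnea,
#' Orthopnea and Respiratory insufficiency; for uniformity with the original
#' scale the Dyspnea value is taken as the single respiratory score.
#'
#' @param r1_dyspnea,r2_orthopnea,r3_resp_insuff Integer vectors in `{0..4}`
#'   (NA allowed).
#' @return The Dyspnea values.
#' @export
collapse_respiratory <- function(r1_dyspnea, r2_orthopnea, r3_resp_insuff) {
  vals <- c(r1_dyspnea, r2_orthopnea, r3_resp_insuff)
  if (any(!is.na(vals) & (vals < 0 | vals > 4 | vals != floor(vals)))) {
    abort_config("respiratory item values must be integers in {0..4}")
  }
  r1_dyspnea
}

#' Convert an absolute FVC measurement to percent of normal
#'
#' @param absolute Measured forced vital capacity (litres).
#' @param normal Subject's normal value (litres); non-positive or missing
#'   normals yield `NA` (the record stays missing, it is not imputed).
#' @return Percent of normal, `100 * absolute / normal`.
#' @export
fvc_to_percent <- function(absolute, normal) {
  out <- 100 * absolute / normal
  out[is.na(normal) | normal <= 0] <- NA_real_
  out
}

# wide per-visit snapshot of a long (patient_id, visit_day, variable, value)
# table restricted to given (patient, day) pairs; columns prefixed
snapshot_long <- function(long, keys, prefix) {
  if (nrow(long) == 0) {
    return(keys[, "patient_id", drop = FALSE])
  }
  joined <- dplyr::inner_join(long, keys, by = c("patient_id", "visit_day"))
  joined <- dplyr::distinct(joined, .data$patient_id, .data$variable,
                            .keep_all = TRUE)
  wide <- tidyr::pivot_wider(
    joined[, c("patient_id", "variable", "value")],
    names_from = "variable", values_from = "value",
    names_prefix = prefix
  )
  dplyr::left_join(keys[, "patient_id", drop = FALSE], wide, by = "patient_id")
}

#' Build the uniform first/last-visit patient dataset
#'
#' Applies the preparation rules: revised respiratory scores are collapsed
#' to the Dyspnea value; FVC is converted to percent of normal; per patient
#' only the earliest and latest visit with a fully documented ALSFRS vector
#' are kept; patients without two such visits are dropped; temporal
#' variables missing in more than `drop_threshold` of their instantiation
#' columns are removed; remaining patients missing any retained variable are
#' dropped (complete cases).
#'
#' @param tables Named list of raw tables as produced by [simulate_cohort()]
#'   (`demographics`, `alshx`, `riluzole`, `alsfrs`, `fvc`, `labs`,
#'   `vitals`), or an `als_cohort`.
#' @param drop_threshold Fraction of missing values above which a temporal
#'   variable column is dropped rather than its patients. Default 0.4.
#'
#' @return A list of class `als_dataset`:
#'   \describe{
#'     \item{data}{one row per surviving patient: `patient_id`, statics
#'       (`age`, `gender`, `onset_site`, `onset_delta`, `riluzole`),
#'       temporal variables as `<name>_first` / `<name>_last`, ALSFRS items
#'       as `alsfrs_<item>_first` / `_last`, and `time_var` (days).}
#'     \item{log}{tibbles `dropped_patients` (id, reason) and
#'       `dropped_variables` (column, missing fraction).}
#'   }
#' @export
build_patient_dataset <- function(tables, drop_threshold = 0.4) {
  if (inherits(tables, "als_cohort")) tables <- tables$tables
  items <- alsfrs_items()

  af <- tibble::as_tibble(tables$alsfrs)
  if (all(c("scale", "r1_dyspnea") %in% names(af)) && nrow(af) > 0) {
    rev_rows <- !is.na(af$scale) & af$scale == "ALSFRS-R"
    af$respiratory[rev_rows] <- collapse_respiratory(
      af$r1_dyspnea[rev_rows], af$r2_orthopnea[rev_rows],
      af$r3_resp_insuff[rev_rows])
  }
  af <- af[, c("patient_id", "visit_day", items)]

  documented <- af[complete.cases(af[, items]), ]
  all_ids <- unique(tables$demographics$patient_id)

  dropped <- tibble::tibble(patient_id = character(), reason = character())
  n_doc <- table(documented$patient_id)
  no_alsfrs <- setdiff(all_ids, names(n_doc))
  single <- names(n_doc)[n_doc < 2]
  # patients whose documented visits all share one day count as single-visit
  if (length(dropped) >= 0) {
    days_per <- tapply(documented$visit_day, documented$patient_id,
                       function(d) length(unique(d)))
    single <- union(single, names(days_per)[days_per < 2])
  }
  dropped <- dplyr::bind_rows(
    dropped,
    tibble::tibble(patient_id = no_alsfrs, reason = "no documented ALSFRS"),
    tibble::tibble(patient_id = single, reason = "fewer than two ALSFRS visits")
  )
  keep_ids <- setdiff(all_ids, dropped$patient_id)

  documented <- documented[documented$patient_id %in% keep_ids, ]
  documented <- dplyr::arrange(documented, .data$patient_id, .data$visit_day)
  firsts <- dplyr::slice_head(dplyr::group_by(documented, .data$patient_id), n = 1)
  lasts <- dplyr::slice_tail(dplyr::group_by(documented, .data$patient_id), n = 1)
  firsts <- dplyr::ungroup(firsts); lasts <- dplyr::ungroup(lasts)

  key_first <- firsts[, c("patient_id", "visit_day")]
  key_last <- lasts[, c("patient_id", "visit_day")]

  fvc <- tibble::as_tibble(tables$fvc)
  if (!"fvc_percent" %in% names(fvc)) {
    fvc$fvc_percent <- fvc_to_percent(fvc$fvc_liters, fvc$fvc_normal)
  } else {
    need <- is.na(fvc$fvc_percent)
    fvc$fvc_percent[need] <- fvc_to_percent(fvc$fvc_liters[need],
                                            fvc$fvc_normal[need])
  }
  fvc_long <- tibble::tibble(patient_id = fvc$patient_id,
                             visit_day = fvc$visit_day,
                             variable = "fvc_percent",
                             value = fvc$fvc_percent)
  labs <- tibble::as_tibble(tables$labs)
  labs$variable <- paste0("lab_", labs$variable)
  vitals <- tibble::as_tibble(tables$vitals)
  vitals$variable <- paste0("vital_", vitals$variable)
  temporal <- dplyr::bind_rows(labs, vitals, fvc_long)
  temporal <- temporal[!is.na(temporal$value), ]

  snap_first <- snapshot_long(temporal, key_first, "")
  snap_last <- snapshot_long(temporal, key_last, "")
  names(snap_first)[-1] <- paste0(names(snap_first)[-1], "_first")
  names(snap_last)[-1] <- paste0(names(snap_last)[-1], "_last")

  af_first <- firsts
  names(af_first)[match(items, names(af_first))] <- paste0("alsfrs_", items, "_first")
  af_last <- lasts
  names(af_last)[match(items, names(af_last))] <- paste0("alsfrs_", items, "_last")

  statics <- tibble::as_tibble(tables$demographics)
  statics <- dplyr::left_join(statics, tibble::as_tibble(tables$alshx),
                              by = "patient_id")
  statics <- dplyr::left_join(statics, tibble::as_tibble(tables$riluzole),
                              by = "patient_id")

  data <- statics[statics$patient_id %in% keep_ids, ]
  data <- dplyr::left_join(data, snap_first, by = "patient_id")
  data <- dplyr::left_join(data, snap_last, by = "patient_id")
  data <- dplyr::left_join(
    data, dplyr::rename(af_first, first_day = "visit_day"), by = "patient_id")
  data <- dplyr::left_join(
    data, dplyr::rename(af_last, last_day = "visit_day"), by = "patient_id")
  data$time_var <- data$last_day - data$first_day
  data$first_day <- NULL
  data$last_day <- NULL

  # variable-level drop rule: temporal columns too sparse are removed
  temporal_cols <- grep("^(lab_|vital_|fvc_percent)", names(data), value = TRUE)
  miss_frac <- purrr::map_dbl(temporal_cols, ~ mean(is.na(data[[.x]])))
  names(miss_frac) <- temporal_cols
  drop_cols <- temporal_cols[miss_frac > drop_threshold]
  dropped_vars <- tibble::tibble(column = drop_cols,
                                 missing_frac = unname(miss_frac[drop_cols]))
  data <- data[, setdiff(names(data), drop_cols)]

  # complete-case rule over every retained variable
  incomplete <- !complete.cases(data)
  dropped <- dplyr::bind_rows(
    dropped,
    tibble::tibble(patient_id = data$patient_id[incomplete],
                   reason = "missing retained variable")
  )
  data <- data[!incomplete, ]

  structure(
    list(data = tibble::as_tibble(data),
         log = list(dropped_patients = dropped, dropped_variables = dropped_vars),
         drop_threshold = drop_threshold),
    class = "als_dataset"
  )
}

#' @export
print.als_dataset <- function(x, ...) {
  cat("<als_dataset> ", nrow(x$data), " patients, ",
      ncol(x$data) - 1, " variables; ",
      nrow(x$log$dropped_patients), " patients and ",
      nrow(x$log$dropped_variables), " variables dropped\n", sep = "")
  invisible(x)
}

static_columns <- function() {
  c("age", "gender", "onset_site", "onset_delta", "riluzole")
}

#' Assemble a per-setting, per-item modelling table
#'
#' Builds the flat patients-by-features table for one semi-temporal setting
#' and one ALSFRS target item.  Feature sets by setting:
#' \describe{
#'   \item{last}{static variables + last-visit temporal variables.}
#'   \item{both}{statics + first-visit + last-visit temporal variables +
#'     `time_var` (days between the visits).}
#'   \item{first}{statics + first-visit temporal variables + `time_var`.}
#' }
#' The target is always the last-visit value of the chosen item.  No ALSFRS
#' item — first- or last-visit — ever appears among the features, so the
#' models must map physiological and laboratory measurements to disease
#' state rather than letting functional scores predict themselves.
#'
#' @param dataset An `als_dataset` (or its `data` tibble).
#' @param setting One of `"last"`, `"both"`, `"first"`.
#' @param target_item One of [alsfrs_items()].
#' @return A tibble of class `als_modeling_table` with columns `patient_id`,
#'   the feature columns, and integer `target` in `{0..4}`; attributes
#'   `setting`, `target_item` and `features`.
#' @export
assemble_setting <- function(dataset, setting = c("last", "both", "first"),
                             target_item) {
  setting <- match.arg(setting)
  target_item <- validate_items(target_item)
  data <- if (inherits(dataset, "als_dataset")) dataset$data else
    tibble::as_tibble(dataset)

  temporal_first <- grep("^(lab_|vital_|fvc_percent).*_first$", names(data),
                         value = TRUE)
  temporal_last <- grep("^(lab_|vital_|fvc_percent).*_last$", names(data),
                        value = TRUE)
  feats <- switch(setting,
    last = c(static_columns(), temporal_last),
    both = c(static_columns(), temporal_first, temporal_last, "time_var"),
    first = c(static_columns(), temporal_first, "time_var")
  )
  feats <- intersect(feats, names(data))
  target_col <- paste0("alsfrs_", target_item, "_last")
  if (!target_col %in% names(data)) {
    abort_config(paste("dataset lacks target column", target_col))
  }
  out <- data[, c("patient_id", feats)]
  out$target <- as.integer(data[[target_col]])
  structure(out, class = c("als_modeling_table", class(tibble::tibble())),
            setting = setting, target_item = target_item, features = feats)
}

#' Feature column names of a modelling table
#' @param table An `als_modeling_table`.
#' @return Character vector of feature column names.
#' @export
table_features <- function(table) {
  attr(table, "features") %||% setdiff(names(table), c("patient_id", "target"))
}
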