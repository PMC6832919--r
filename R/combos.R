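# Severe/mild stratification and value-combination frequency analysis
# over four important Markov-blanket variables per ALSFRS item.

#' Split patients into severe and mild groups by a last-visit item value
#'
#' Severe patients score 0 or 1 on the item at the last clinic visit, mild
#' patients 3 or 4; patients at 2 are excluded from both groups.
#'
#' @param data Data frame with `patient_id` and the item value column.
#' @param item_col Column holding the last-visit item value (default
#'   `"target"`).
#' @return A list of class `als_severity_groups`: `severe`, `mild`,
#'   `excluded` (character patient-id vectors).
#' @export
split_severity <- function(data, item_col = "target") {
  data <- tibble::as_tibble(data)
  v <- as.numeric(data[[item_col]])
  if (any(!is.na(v) & (v < 0 | v > 4))) {
    abort_config("item values must lie in {0..4}")
  }
  ids <- as.character(data$patient_id %||% seq_len(nrow(data)))
  ok <- !is.na(v)
  out <- list(severe = ids[ok & v <= 1],
              mild = ids[ok & v >= 3],
              excluded = ids[ok & v == 2])
  if (length(out$severe) == 0 || length(out$mild) == 0) {
    rlang::warn("empty severe or mild group")
  }
  structure(out, class = "als_severity_groups")
}

#' Select the four analysis variables for an item
#'
#' The four Markov-blanket variables with the highest normalised
#' importance (VLi) for the item; when the blanket holds fewer than four
#' variables all of them are returned with a flag.  Importance entries are
#' matched to blanket variables by base name, ignoring `_first`/`_last`
#' instantiation suffixes.
#'
#' @param mb Character vector (a Markov blanket) or an `als_bn`.
#' @param importance An `als_importance` table for the item.
#' @return Character vector (<= 4) with attribute `short_set` when fewer
#'   than four were available.
#' @export
select_four_variables <- function(mb, importance) {
  if (inherits(mb, "als_bn")) mb <- markov_blanket(mb)
  imp <- tibble::as_tibble(importance)
  imp$base <- sub("_(first|last)$", "", imp$predictor)
  mb_base <- sub("_(first|last)$", "", mb)
  score <- vapply(mb_base, function(b) {
    s <- imp$vli[imp$base == b]
    if (length(s) == 0) 0 else max(s)
  }, numeric(1))
  ord <- order(-score, mb)
  out <- mb[ord][seq_len(min(4, length(mb)))]
  if (length(mb) < 4) {
    rlang::warn("Markov blanket holds fewer than four variables")
    attr(out, "short_set") <- TRUE
  }
  out
}

#' Frequencies of variable value combinations in severe and mild patients
#'
#' For each possible combination of the (discretized) analysis variables,
#' the relative frequency among severe and among mild patients; each
#' group's column sums to 100.  Patients missing any analysis value are
#' excluded from both denominators.
#'
#' @param data Discrete data frame with `patient_id` and the analysis
#'   variables.
#' @param variables Character vector of analysis variable columns
#'   (typically four).
#' @param groups An `als_severity_groups`.
#' @param top_k How many top combinations to flag per group (default 6,
#'   ties broken by combination lexicographic order).
#' @return A tibble of class `als_combination_table`: one row per level
#'   combination with `severe_pct`, `mild_pct`, `severe_rank`, `mild_rank`,
#'   `top_severe`, `top_mild`; attributes `n_severe`, `n_mild`.
#' @export
combination_frequencies <- function(data, variables, groups, top_k = 6L) {
  data <- tibble::as_tibble(data)
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars) > 0) {
    abort_config(paste("variables not in data:",
                       paste(missing_vars, collapse = ", ")))
  }
  ids <- as.character(data$patient_id %||% seq_len(nrow(data)))
  complete <- complete.cases(data[variables])
  if (any(!complete)) {
    rlang::warn(sprintf("%d patient(s) missing an analysis value excluded",
                        sum(!complete)))
  }
  vals <- dplyr::mutate(data[variables],
                        dplyr::across(dplyr::everything(), as.character))
  level_sets <- lapply(vals, function(v) sort(unique(v[complete])))
  grid <- do.call(tidyr::expand_grid, rev(level_sets))
  grid <- grid[, variables]

  count_group <- function(group_ids) {
    sel <- complete & ids %in% group_ids
    n <- sum(sel)
    if (n == 0) return(list(pct = rep(0, nrow(grid)), n = 0))
    key_obs <- do.call(paste, c(vals[sel, ], sep = "\r"))
    key_grid <- do.call(paste, c(grid, sep = "\r"))
    cnt <- table(key_obs)[key_grid]
    cnt[is.na(cnt)] <- 0
    list(pct = 100 * as.numeric(cnt) / n, n = n)
  }
  sev <- count_group(groups$severe)
  mld <- count_group(groups$mild)

  out <- grid
  out$severe_pct <- sev$pct
  out$mild_pct <- mld$pct
  # dense ranking: by descending frequency, lexicographic combination on ties
  lex <- do.call(order, c(list(-out$severe_pct), as.list(grid)))
  out$severe_rank <- integer(nrow(out)); out$severe_rank[lex] <- seq_len(nrow(out))
  lex <- do.call(order, c(list(-out$mild_pct), as.list(grid)))
  out$mild_rank <- integer(nrow(out)); out$mild_rank[lex] <- seq_len(nrow(out))
  out$top_severe <- out$severe_rank <= top_k & out$severe_pct > 0
  out$top_mild <- out$mild_rank <= top_k & out$mild_pct > 0
  structure(out, class = c("als_combination_table", class(out)),
            n_severe = sev$n, n_mild = mld$n, variables = variables,
            top_k = top_k)
}

#' Quartile discretization of FVC percent into four labelled levels
#'
#' Forces percent-of-normal FVC into `low`, `moderate_low`,
#' `moderate_high`, `high` by sample quartiles — used when the supervised
#' MDL scheme yields fewer levels than the combination analysis displays.
#'
#' @param values Numeric FVC percent values.
#' @return Character vector over the four labels.
#' @export
fvc_quartile_levels <- function(values) {
  br <- unique(quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE))
  labs <- c("low", "moderate_low", "moderate_high", "high")[seq_len(length(br) - 1)]
  as.character(cut(values, breaks = br, labels = labs, include.lowest = TRUE))
}
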