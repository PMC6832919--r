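# Variance-based predictor importance (first-order sensitivity).
#
# For predictor X and ordinal target Y, Si = V(E[Y|X]) / V(Y) — the
# fraction of target variance removed by knowing X — estimated by exact
# conditional means on the (binned) empirical distribution.  Normalised
# importances VLi = Si / sum_j Sj are ranked per ALSFRS item and averaged
# over items and over the first-/last-visit instantiations of a variable.

pop_var <- function(x) mean((x - mean(x))^2)

bin_predictor <- function(x, bins) {
  if (!is.numeric(x) || length(unique(x)) <= bins) return(as.character(x))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE))
  if (length(br) < 2) return(as.character(x))
  as.character(cut(x, breaks = br, include.lowest = TRUE))
}

#' First-order sensitivity of an ordinal target to one predictor
#'
#' `Si = V(E[Y|Xi]) / V(Y)` with population variances computed on the
#' empirical distribution; continuous predictors are binned into deciles
#' (configurable) so the conditional means are exact group means.  By the
#' law of total variance Si always lies in `[0, 1]`.
#'
#' @param data Data frame. @param predictor,target Column names.
#' @param bins Number of quantile bins for continuous predictors.
#' @return Scalar in `[0, 1]`, or `NA` (with a warning) when `V(Y) = 0`.
#' @export
sensitivity <- function(data, predictor, target = "target", bins = 10L) {
  data <- tibble::as_tibble(data)
  y <- as.numeric(data[[target]])
  x <- data[[predictor]]
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  vy <- pop_var(y)
  if (vy == 0 || length(y) == 0) {
    rlang::warn(paste0("target variance is zero; sensitivity undefined for ",
                       predictor))
    return(NA_real_)
  }
  g <- bin_predictor(x, bins)
  cond_means <- tapply(y, g, mean)
  weights <- as.numeric(table(g)[names(cond_means)]) / length(y)
  ve <- sum(weights * (cond_means - mean(y))^2)
  ve / vy
}

#' Rank predictors by normalised sensitivity
#'
#' Computes Si for each predictor, normalises to `VLi = Si / sum(Sj)`, and
#' ranks in decreasing importance (ties broken alphabetically).  If every
#' Si is zero the VLi are uniform, with a warning.
#'
#' @param data Data frame. @param predictors Predictor columns; default all
#'   feature columns. @param target Target column. @param bins See
#'   [sensitivity()].
#' @return Tibble of class `als_importance`: `predictor`, `si`, `vli`,
#'   `rank`; attribute `item` when the input was a modelling table.
#' @export
rank_importance <- function(data, predictors = NULL, target = "target",
                            bins = 10L) {
  data_tbl <- tibble::as_tibble(data)
  if (is.null(predictors)) {
    predictors <- if (inherits(data, "als_modeling_table")) table_features(data)
    else setdiff(names(data_tbl), c(target, "patient_id"))
  }
  si <- vapply(predictors, function(p) {
    sensitivity(data_tbl, p, target, bins)
  }, numeric(1))
  defined <- !is.na(si)
  if (!any(defined)) abort_config("no predictor has a defined sensitivity")
  si_d <- si[defined]
  if (sum(si_d) == 0) {
    rlang::warn("all sensitivities are zero; uniform importance assigned")
    vli <- rep(1 / length(si_d), length(si_d))
  } else {
    vli <- si_d / sum(si_d)
  }
  out <- tibble::tibble(predictor = predictors[defined], si = si_d, vli = vli)
  out <- out[order(-out$vli, out$predictor), ]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("als_importance", class(out)),
            item = attr(data, "target_item"))
}

#' Average importance over items and variable instantiations
#'
#' Given per-item importance tables whose predictors may appear as
#' first-visit and last-visit instantiations (`<name>_first` /
#' `<name>_last`), averages VLi per base variable over all items and both
#' instantiations.  Variables present in only some reports are averaged
#' over the reports where they appear and flagged.
#'
#' @param reports Named list (by item) of [rank_importance()] results.
#' @return Tibble `variable`, `mean_vli`, `n_entries`, `in_all_reports`,
#'   `rank`.
#' @export
average_importance <- function(reports) {
  long <- purrr::imap_dfr(reports, function(rep, item) {
    tibble::tibble(item = item, predictor = rep$predictor, vli = rep$vli)
  })
  long$variable <- sub("_(first|last)$", "", long$predictor)
  # mean over a variable's instantiations within an item, then over items
  per_item <- dplyr::summarise(
    dplyr::group_by(long, .data$item, .data$variable),
    vli = mean(.data$vli), n = dplyr::n(), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(per_item, .data$variable),
    mean_vli = mean(.data$vli),
    n_entries = sum(.data$n),
    n_items = dplyr::n(),
    .groups = "drop")
  out$in_all_reports <- out$n_items == length(reports)
  if (any(!out$in_all_reports)) {
    rlang::warn("some variables are present in only a subset of the reports")
  }
  out <- out[order(-out$mean_vli, out$variable), ]
  out$rank <- seq_len(nrow(out))
  out[, c("variable", "mean_vli", "n_entries", "in_all_reports", "rank")]
}
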