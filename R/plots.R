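# ggplot2 displays for the main result types.

#' Plot a pooled confusion matrix
#'
#' @param eval An `als_eval`. @param model Model name (defaults to the
#'   first).
#' @return A ggplot tile plot of observed vs predicted counts.
#' @export
plot_confusion <- function(eval, model = NULL) {
  model <- model %||% names(eval$confusion)[1]
  cm <- eval$confusion[[model]]
  df <- tibble::as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("observed", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = paste("Confusion matrix:", model),
                  x = "predicted class", y = "observed class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.als_eval <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$model, y = .data$mae)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "per-fold MAE (ALSFRS points)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.als_importance <- function(object, top_n = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$predictor, .data$vli), y = .data$vli)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalised importance (VLi)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.als_feature_selection <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$accuracy)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$accuracy)) +
    ggplot2::geom_vline(xintercept = attr(object, "best_k"),
                        linetype = "dashed") +
    ggplot2::labs(x = "subset size k", y = "validation accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.als_grouping <- function(object, ...) {
  cm <- object$correlation
  df <- tibble::as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("item_a", "item_b", "correlation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item_a, y = .data$item_b,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Long bar-chart-ready form of a combination table
#'
#' @param combos An `als_combination_table`.
#' @return Tibble `combination`, `group`, `pct`.
#' @export
combination_long <- function(combos) {
  vars <- attr(combos, "variables")
  df <- tibble::as_tibble(combos)
  df$combination <- do.call(paste, c(df[vars], sep = " / "))
  tidyr::pivot_longer(df[, c("combination", "severe_pct", "mild_pct")],
                      cols = c("severe_pct", "mild_pct"),
                      names_to = "group", values_to = "pct",
                      names_pattern = "(.*)_pct")
}

#' @export
autoplot.als_combination_table <- function(object, top_only = TRUE, ...) {
  df <- tibble::as_tibble(object)
  if (top_only) df <- df[df$top_severe | df$top_mild, ]
  long <- combination_long(
    structure(df, variables = attr(object, "variables"),
              class = class(object)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$combination, y = .data$pct,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "patients (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
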