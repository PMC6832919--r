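# Feature selection by the J3 scatter criterion.
#
# J3 = trace(W^-1 B) with W the pooled within-class scatter matrix and B
# the between-class scatter matrix; it is large when classes are compact
# and well separated, and is invariant to invertible linear transforms of
# the feature space.  Subsets of each size k are ranked by J3 and the final
# size is chosen by the validation accuracy of a pluggable classifier.

as_numeric_matrix <- function(data, cols) {
  out <- lapply(data[cols], function(v) {
    if (is.numeric(v)) as.numeric(v) else as.numeric(as.factor(v))
  })
  m <- do.call(cbind, out)
  colnames(m) <- cols
  m
}

scatter_matrices <- function(x, labels) {
  x <- as.matrix(x)
  cls <- unique(labels)
  if (length(cls) < 2) abort_config("need at least two classes for scatter")
  p <- ncol(x)
  mu <- colMeans(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (c in cls) {
    xi <- x[labels == c, , drop = FALSE]
    prior <- nrow(xi) / nrow(x)
    mui <- colMeans(xi)
    centred <- sweep(xi, 2, mui)
    W <- W + prior * crossprod(centred) / max(nrow(xi), 1)
    d <- mui - mu
    B <- B + prior * tcrossprod(d)
  }
  list(within = W, between = B,
       priors = as.numeric(table(labels)[as.character(cls)]) / nrow(x))
}

#' J3 scatter-criterion score of a feature subset
#'
#' Computes `trace(W^-1 B)` for the given feature matrix, where `W` is the
#' prior-weighted pooled within-class scatter and `B` the between-class
#' scatter of the class means.  A small ridge
#' (`ridge * mean(diag(W))`) is added to `W` before inversion because
#' collinear laboratory panels are expected.
#'
#' @param x Numeric matrix or data frame (rows = records, columns = the
#'   candidate subset).
#' @param labels Class labels (>= 2 distinct values present).
#' @param ridge Relative ridge added to the diagonal of `W`. Default 1e-8.
#' @return Non-negative scalar; 0 when all class means coincide.
#' @export
j3_score <- function(x, labels, ridge = 1e-8) {
  x <- as.matrix(x)
  sc <- scatter_matrices(x, labels)
  W <- sc$within
  diag(W) <- diag(W) + ridge * mean(diag(W))
  inv <- tryCatch(solve(W, sc$between), error = function(e) NULL)
  if (is.null(inv)) {
    degen <- colnames(x)[apply(sc$within, 1, function(r) all(abs(r) < 1e-12))]
    rlang::abort(paste0("within-class scatter is singular after ridge",
                        if (length(degen)) paste0(" (offending features: ",
                                                  paste(degen, collapse = ", "), ")")),
                 class = "alsord_numeric_error")
  }
  max(sum(diag(inv)), 0)
}

#' Best feature subset of a given size under J3
#'
#' Searches the subsets of size `k` for the J3 maximiser.  The search is
#' exhaustive when `choose(p, k)` does not exceed `max_exhaustive`
#' (provably optimal), otherwise sequential forward selection is used.
#'
#' @param data Data frame or matrix of candidate features.
#' @param labels Class labels.
#' @param k Subset size.
#' @param strategy `"auto"` (default), `"exhaustive"` or `"forward"`.
#' @param max_exhaustive Largest number of subsets enumerated under `auto` (default 2e4).
#' @param standardize Standardize columns to zero mean / unit variance
#'   first (mixed laboratory units). Default TRUE.
#' @return List with `features`, `k`, `j3`, `strategy`.
#' @export
select_per_size <- function(data, labels, k,
                            strategy = c("auto", "exhaustive", "forward"),
                            max_exhaustive = 2e4, standardize = TRUE) {
  strategy <- match.arg(strategy)
  x <- if (is.matrix(data)) data else as_numeric_matrix(tibble::as_tibble(data),
                                                        colnames(data))
  p <- ncol(x)
  if (k < 1 || k > p) abort_config("k must lie in [1, number of features]")
  if (standardize) {
    sds <- apply(x, 2, sd)
    sds[sds == 0] <- 1
    x <- scale(x, scale = sds)
  }
  if (strategy == "auto") {
    strategy <- if (choose(p, k) <= max_exhaustive) "exhaustive" else "forward"
  }
  if (strategy == "exhaustive") {
    sets <- combn(p, k)
    scores <- apply(sets, 2, function(ix) j3_score(x[, ix, drop = FALSE], labels))
    best <- which.max(scores)
    sel <- sets[, best]
    best_j3 <- scores[best]
  } else {
    sel <- integer(0)
    for (step in seq_len(k)) {
      cand <- setdiff(seq_len(p), sel)
      scores <- vapply(cand, function(j) {
        j3_score(x[, c(sel, j), drop = FALSE], labels)
      }, numeric(1))
      sel <- c(sel, cand[which.max(scores)])
    }
    best_j3 <- j3_score(x[, sel, drop = FALSE], labels)
    sel <- sort(sel)
  }
  list(features = colnames(x)[sel], k = k, j3 = best_j3, strategy = strategy)
}

#' Two-layer perceptron validator
#'
#' Returns a fit/predict closure for [select_features()]: a single hidden
#' layer perceptron with `ceiling(k/2)` hidden units for subsets of fewer
#' than ten features and 10 units otherwise.
#'
#' @param decay Weight decay. @param maxit Max iterations.
#' @return Function `(train_x, train_y, new_x) -> predicted classes`.
#' @export
validator_nnet <- function(decay = 1e-3, maxit = 150) {
  function(train_x, train_y, new_x) {
    k <- ncol(train_x)
    size <- if (k < 10) ceiling(k / 2) else 10L
    y <- factor(train_y)
    fit <- nnet::nnet(x = train_x, y = nnet::class.ind(y), size = max(size, 1),
                      softmax = nlevels(y) > 1, decay = decay, maxit = maxit,
                      trace = FALSE, MaxNWts = 5000)
    pr <- predict(fit, new_x)
    levels(y)[max.col(pr)]
  }
}

#' Feature selection across subset sizes by J3 and validation accuracy
#'
#' For each size `k` in `1..K` finds the J3-best subset of the candidate
#' features, trains the validator on a training split restricted to that
#' subset, and measures accuracy on a held-out validation split; the subset
#' with the highest validation accuracy is returned, ties broken toward the
#' smaller size.
#'
#' @param data Data frame holding features and the target column, e.g. an
#'   `als_modeling_table`.
#' @param target Name of the target column (default `"target"`).
#' @param features Candidate feature columns; defaults to every numeric
#'   column except `target` and `patient_id`.
#' @param K Maximal subset size (default 25, capped at the pool size).
#' @param validator Fit/predict closure, default [validator_nnet()].
#' @param validation_frac Held-out fraction (default 0.25).
#' @param seed Seed for the split and the validator.
#' @param ... Passed to [select_per_size()].
#' @return A tibble of class `als_feature_selection` with one row per `k`
#'   (`k`, `j3`, `accuracy`, list-column `features`) and attributes
#'   `best_k`, `best_features`.
#' @export
select_features <- function(data, target = "target", features = NULL, K = 25,
                            validator = validator_nnet(),
                            validation_frac = 0.25, seed = 1L, ...) {
  data <- tibble::as_tibble(data)
  if (is.null(features)) {
    features <- setdiff(names(data), c(target, "patient_id"))
    features <- features[purrr::map_lgl(data[features], is.numeric)]
  }
  y <- data[[target]]
  x <- as_numeric_matrix(data, features)
  K <- min(K, length(features))

  with_seed(seed, {
    n <- nrow(x)
    for (attempt in 1:20) {
      val_idx <- sample.int(n, max(1, round(validation_frac * n)))
      if (length(unique(y[-val_idx])) >= 2 && length(val_idx) < n) break
      rlang::warn("degenerate validation split; re-splitting")
    }
    rows <- purrr::map(seq_len(K), function(k) {
      sel <- select_per_size(x, y, k, ...)
      pred <- validator(x[-val_idx, sel$features, drop = FALSE], y[-val_idx],
                        x[val_idx, sel$features, drop = FALSE])
      acc <- mean(as.character(pred) == as.character(y[val_idx]))
      tibble::tibble(k = k, j3 = sel$j3, accuracy = acc,
                     features = list(sel$features))
    })
    out <- dplyr::bind_rows(rows)
    best <- which.max(out$accuracy)   # first max -> smallest k on ties
    structure(out,
              class = c("als_feature_selection", class(out)),
              best_k = out$k[best],
              best_features = out$features[[best]])
  })
}

#' Selected features of an `als_feature_selection`
#' @param selection Result of [select_features()].
#' @return Character vector of the winning subset.
#' @export
selected_features <- function(selection) {
  attr(selection, "best_features")
}

#' Selection-count summary over items
#'
#' Given per-item selection results, counts how often each candidate
#' feature was chosen — the per-variable participation summary.
#'
#' @param selections Named list (by item) of `als_feature_selection`
#'   objects or plain character vectors of selected features.
#' @return Tibble `feature`, `n_selected`, `items` (list-column).
#' @export
count_feature_selections <- function(selections) {
  sel_sets <- purrr::map(selections, function(s) {
    if (is.character(s)) s else selected_features(s)
  })
  long <- tibble::tibble(
    item = rep(names(sel_sets), lengths(sel_sets)),
    feature = unlist(sel_sets, use.names = FALSE)
  )
  out <- dplyr::summarise(dplyr::group_by(long, .data$feature),
                          n_selected = dplyr::n(),
                          items = list(.data$item), .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$n_selected), .data$feature)
}
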