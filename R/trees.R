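# Decision-tree learners written for the five-category ALSFRS targets:
#
#  * a multi-class tree split by information gain ratio with
#    reduced-error pruning on a validation fold (the C5.0-style baseline;
#    C5.0 itself is proprietary),
#  * an ordinal decision tree (ODT) whose impurity is the sum of absolute
#    deviations from the node's weighted median label, so both splitting
#    and leaf prediction respect ordinal distances,
#  * cumulative probability trees (CPT): four binary gain-ratio trees for
#    the targets 1{y > k}, k = 0..3, differenced into class probabilities.
#
# All trees share one recursive grower; labels are coded 1..K internally.

entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# sum of absolute deviations from the weighted median, from class counts
# (classes are the integers `values`)
abs_cost_counts <- function(counts, values) {
  n <- sum(counts)
  if (n == 0) return(0)
  m <- values[which(cumsum(counts) >= n / 2)[1]]
  sum(counts * abs(values - m))
}

median_from_counts <- function(counts, values) {
  n <- sum(counts)
  values[which(cumsum(counts) >= n / 2)[1]]
}

# vectorized split scores over all prefixes of a sorted column ------------

# C: B x K prefix count matrix (rows = candidate left branches),
# tot: length-K total counts.  Returns per-row split scores: for the
# ordinal criterion the decrease in summed absolute deviation from the
# child medians, with a small squared-error term breaking the frequent
# exact ties of the median-based criterion; for the nominal criterion the
# information gain ratio.
split_scores <- function(C, tot, type, values) {
  n <- sum(tot)
  K <- length(tot)
  nl <- rowSums(C)
  nr <- n - nl
  R <- matrix(tot, nrow = nrow(C), ncol = K, byrow = TRUE) - C
  if (type == "ordinal") {
    UT <- (upper.tri(diag(K), diag = TRUE)) * 1   # cumulate over classes
    CCl <- C %*% UT
    CCr <- R %*% UT
    medl <- max.col(CCl >= nl / 2, "first")
    medr <- max.col(CCr >= pmax(nr, 1) / 2, "first")
    A <- abs(outer(values, values, "-"))          # |class - median| lookup
    cl <- rowSums(C * A[medl, , drop = FALSE])
    cr <- rowSums(R * A[medr, , drop = FALSE])
    mae_gain <- abs_cost_counts(tot, values) - (cl + cr)
    sl <- as.numeric(C %*% values); ql <- as.numeric(C %*% values^2)
    sr <- as.numeric(R %*% values); qr <- as.numeric(R %*% values^2)
    sse <- (ql - sl^2 / pmax(nl, 1)) + (qr - sr^2 / pmax(nr, 1))
    sse_parent <- sum(tot * values^2) - sum(tot * values)^2 / n
    sse_gain <- sse_parent - sse
    w <- getOption("alsord.odt_sse_weight", 1e-6)
    mae_gain + w * sse_gain
  } else {
    row_entropy <- function(M, nn) {
      P <- M / pmax(nn, 1)
      rowSums(ifelse(P > 0, -P * log2(P), 0))
    }
    hl <- row_entropy(C, nl)
    hr <- row_entropy(R, nr)
    hp <- entropy_counts(tot)
    ig <- hp - (nl * hl + nr * hr) / n
    pl <- nl / n; pr <- nr / n
    si <- -(ifelse(pl > 0, pl * log2(pl), 0) + ifelse(pr > 0, pr * log2(pr), 0))
    ifelse(si > 1e-12, ig / si, -Inf)
  }
}

find_best_split <- function(x, y_idx, idx, K, type, values, min_leaf) {
  best <- NULL
  best_score <- 1e-12
  n <- length(idx)
  tot <- tabulate(y_idx[idx], K)
  for (v in names(x)) {
    xv <- x[[v]][idx]
    if (is.numeric(xv)) {
      o <- order(xv)
      xs <- xv[o]
      ys <- y_idx[idx][o]
      bnd <- which(diff(xs) > 0)
      bnd <- bnd[bnd >= min_leaf & (n - bnd) >= min_leaf]
      if (length(bnd) == 0) next
      M <- matrix(0L, n, K)
      M[cbind(seq_len(n), ys)] <- 1L
      Ccum <- apply(M, 2, cumsum)
      C <- Ccum[bnd, , drop = FALSE]
      sc <- split_scores(C, tot, type, values)
      j <- which.max(sc)
      if (length(j) && sc[j] > best_score) {
        best_score <- sc[j]
        best <- list(var = v, type = "num",
                     threshold = (xs[bnd[j]] + xs[bnd[j] + 1]) / 2,
                     score = sc[j])
      }
    } else {
      lv <- unique(as.character(xv))
      if (length(lv) < 2) next
      C <- t(vapply(lv, function(l) tabulate(y_idx[idx][xv == l], K),
                    integer(K)))
      keep <- rowSums(C) >= min_leaf & (n - rowSums(C)) >= min_leaf
      if (!any(keep)) next
      sc <- split_scores(C[keep, , drop = FALSE], tot, type, values)
      j <- which.max(sc)
      if (length(j) && sc[j] > best_score) {
        best_score <- sc[j]
        best <- list(var = v, type = "cat", level = lv[keep][j], score = sc[j])
      }
    }
  }
  best
}

grow_tree <- function(x, y_idx, idx, K, type, values, depth,
                      max_depth, min_split, min_leaf) {
  counts <- tabulate(y_idx[idx], K)
  pred_idx <- if (type == "ordinal") {
    which(values == median_from_counts(counts, values))
  } else which.max(counts)
  imp <- if (type == "ordinal") abs_cost_counts(counts, values) else
    entropy_counts(counts)
  leaf <- list(leaf = TRUE, n = length(idx), counts = counts,
               pred = pred_idx)
  if (depth >= max_depth || length(idx) < min_split || imp <= 0) return(leaf)
  sp <- find_best_split(x, y_idx, idx, K, type, values, min_leaf)
  if (is.null(sp)) return(leaf)
  go_left <- if (sp$type == "num") x[[sp$var]][idx] <= sp$threshold else
    as.character(x[[sp$var]][idx]) == sp$level
  lidx <- idx[go_left]; ridx <- idx[!go_left]
  if (length(lidx) == 0 || length(ridx) == 0) return(leaf)
  list(leaf = FALSE, n = length(idx), counts = counts, pred = pred_idx,
       split = sp, majority_left = length(lidx) >= length(ridx),
       left = grow_tree(x, y_idx, lidx, K, type, values, depth + 1,
                        max_depth, min_split, min_leaf),
       right = grow_tree(x, y_idx, ridx, K, type, values, depth + 1,
                         max_depth, min_split, min_leaf))
}

route_left <- function(node, x, idx) {
  xv <- x[[node$split$var]][idx]
  gl <- if (node$split$type == "num") xv <= node$split$threshold else
    as.character(xv) == node$split$level
  gl[is.na(gl)] <- node$majority_left
  gl
}

# vectorized descent returning the leaf node index list per row
tree_predict_idx <- function(node, x, idx, out_pred, out_counts) {
  if (node$leaf || length(idx) == 0) {
    out_pred[idx] <- node$pred
    if (!is.null(out_counts)) out_counts[idx, ] <- rep(node$counts, each = length(idx))
    return(list(pred = out_pred, counts = out_counts))
  }
  gl <- route_left(node, x, idx)
  r <- tree_predict_idx(node$left, x, idx[gl], out_pred, out_counts)
  tree_predict_idx(node$right, x, idx[!gl], r$pred, r$counts)
}

tree_size <- function(node) {
  if (node$leaf) 1L else 1L + tree_size(node$left) + tree_size(node$right)
}

# pessimistic error pruning on the training counts (C4.5-style): a
# subtree is replaced by a leaf unless its continuity-corrected error
# undercuts the leaf's by more than one standard error
prune_pessimistic <- function(node) {
  n <- node$n
  err_leaf <- n - max(node$counts)
  if (node$leaf) {
    node$pep_err <- err_leaf
    node$pep_leaves <- 1L
    return(node)
  }
  node$left <- prune_pessimistic(node$left)
  node$right <- prune_pessimistic(node$right)
  e_sub <- node$left$pep_err + node$right$pep_err +
    0.5 * (node$left$pep_leaves + node$right$pep_leaves)
  se <- sqrt(max(e_sub * (n - e_sub) / n, 0))
  if (err_leaf + 0.5 <= e_sub + se) {
    return(list(leaf = TRUE, n = n, counts = node$counts, pred = node$pred,
                pep_err = err_leaf, pep_leaves = 1L))
  }
  node$pep_err <- node$left$pep_err + node$right$pep_err
  node$pep_leaves <- node$left$pep_leaves + node$right$pep_leaves
  node
}

# reduced-error pruning against a validation fold; metric_fun(pred_idx,
# y_idx, idx) returns an error to minimize
prune_node <- function(node, x, y_idx, idx, metric_fun) {
  if (node$leaf) return(node)
  gl <- route_left(node, x, idx)
  node$left <- prune_node(node$left, x, y_idx, idx[gl], metric_fun)
  node$right <- prune_node(node$right, x, y_idx, idx[!gl], metric_fun)
  if (length(idx) == 0) return(node)
  sub_pred <- tree_predict_idx(node, x, idx, integer(length(y_idx)), NULL)$pred
  err_sub <- metric_fun(sub_pred[idx], y_idx[idx])
  err_leaf <- metric_fun(rep(node$pred, length(idx)), y_idx[idx])
  if (err_leaf <= err_sub) {
    return(list(leaf = TRUE, n = node$n, counts = node$counts,
                pred = node$pred))
  }
  node
}

# shared fitting front end ------------------------------------------------

prepare_xy <- function(data, target, features) {
  data <- tibble::as_tibble(data)
  if (is.null(features)) {
    features <- if (inherits(data, "als_modeling_table")) table_features(data)
    else setdiff(names(data), c(target, "patient_id"))
  }
  y <- data[[target]]
  if (is.null(y)) abort_config(paste("no target column", target))
  list(x = data[features], y = y, features = features)
}

fit_tree_impl <- function(data, target, features, type, classes,
                          max_depth, min_split, min_leaf,
                          prune, validation_frac, seed) {
  d <- prepare_xy(data, target, features)
  y_chr <- as.character(d$y)
  if (is.null(classes)) classes <- sort(unique(y_chr))
  y_idx <- match(y_chr, classes)
  if (anyNA(y_idx)) abort_config("target values outside the declared classes")
  values <- suppressWarnings(as.numeric(classes))
  if (type == "ordinal" && anyNA(values)) {
    abort_config("ordinal targets must be numeric classes")
  }
  if (anyNA(values)) values <- seq_along(classes)
  K <- length(classes)
  n <- nrow(d$x)
  with_seed(seed, {
    # ordinal trees are pruned by validation MAE on a held-out fold;
    # nominal trees use pessimistic pruning on the training counts
    use_val <- prune && type == "ordinal" && n >= 20
    if (use_val) {
      val_idx <- sample.int(n, max(2, round(validation_frac * n)))
      train_idx <- setdiff(seq_len(n), val_idx)
    } else {
      val_idx <- integer(0)
      train_idx <- seq_len(n)
    }
    root <- grow_tree(d$x, y_idx, train_idx, K, type, values, 0L,
                      max_depth, min_split, min_leaf)
    if (use_val) {
      metric <- function(p, yy) mean(abs(values[p] - values[yy]))
      root <- prune_node(root, d$x, y_idx, val_idx, metric)
    } else if (prune && type == "class") {
      root <- prune_pessimistic(root)
    }
    structure(list(root = root, classes = classes, values = values,
                   type = type, features = d$features, target = target),
              class = "als_tree")
  })
}

#' Multi-class decision tree (gain-ratio splitting, reduced-error pruning)
#'
#' Five-class nominal classifier for an ALSFRS target: binary splits chosen
#' by information gain ratio, leaves predicting the modal class, pruned
#' bottom-up against a held-out validation fold when `prune = TRUE`.
#'
#' @param data Data frame (e.g. an `als_modeling_table`).
#' @param target Target column name.
#' @param features Feature columns; defaults to the table's features.
#' @param classes Class labels; defaults to those observed.
#' @param max_depth,min_split,min_leaf Growth limits.
#' @param prune Prune with a validation fold. @param validation_frac Its size.
#' @param seed Seed for the pruning split.
#' @return An `als_tree` with `predict()` methods for classes and
#'   probabilities.
#' @export
fit_multiclass_tree <- function(data, target = "target", features = NULL,
                                classes = NULL, max_depth = 10L,
                                min_split = 10L, min_leaf = 5L, prune = TRUE,
                                validation_frac = 0.25, seed = 1L) {
  fit_tree_impl(data, target, features, "class", classes, max_depth,
                min_split, min_leaf, prune, validation_frac, seed)
}

#' Ordinal decision tree (absolute-error impurity, median leaves)
#'
#' Binary tree whose split criterion minimises the summed absolute
#' deviation of labels from each child's weighted median, and whose leaves
#' predict the weighted median label; pruning minimises validation MAE.
#' Splitting and prediction therefore both respect the ordinal metric used
#' to evaluate the models.
#'
#' @inheritParams fit_multiclass_tree
#' @return An `als_tree` of type `"ordinal"`.
#' @export
fit_odt <- function(data, target = "target", features = NULL, classes = NULL,
                    max_depth = 10L, min_split = 10L, min_leaf = 5L,
                    prune = TRUE, validation_frac = 0.25, seed = 1L) {
  if (is.null(classes)) {
    y <- tibble::as_tibble(data)[[target]]
    classes <- as.character(sort(unique(as.numeric(y))))
  }
  fit_tree_impl(data, target, features, "ordinal", classes, max_depth,
                min_split, min_leaf, prune, validation_frac, seed)
}

#' @export
predict.als_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- tibble::as_tibble(newdata)
  n <- nrow(newdata)
  x <- newdata[intersect(object$features, names(newdata))]
  counts <- if (type == "prob") matrix(0, n, length(object$classes)) else NULL
  r <- tree_predict_idx(object$root, x, seq_len(n), integer(n), counts)
  if (type == "class") {
    out <- object$classes[r$pred]
    if (!anyNA(suppressWarnings(as.numeric(object$classes)))) {
      out <- as.numeric(out)
    }
    out
  } else {
    p <- r$counts / pmax(rowSums(r$counts), 1)
    colnames(p) <- object$classes
    p
  }
}

#' @export
print.als_tree <- function(x, ...) {
  cat("<als_tree> ", x$type, " tree, ", tree_size(x$root), " nodes, classes {",
      paste(x$classes, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Number of nodes in a fitted tree
#' @param tree An `als_tree`.
#' @return Integer node count (1 = root-only).
#' @export
n_tree_nodes <- function(tree) tree_size(tree$root)

# cumulative probability trees --------------------------------------------

#' Cumulative probability trees for ordinal classification
#'
#' Trains one binary gain-ratio tree per threshold `k = 0..3` for the
#' target `1{y > k}`.  Class probabilities are obtained by differencing the
#' cumulative estimates `P(y > k)` (clipped to be non-increasing at 0 and
#' renormalised); the prediction is the most probable class.
#'
#' @inheritParams fit_multiclass_tree
#' @param classes Ordered numeric class labels, default `0:4`.
#' @return An `als_cpt` model.
#' @export
fit_cpt <- function(data, target = "target", features = NULL, classes = 0:4,
                    max_depth = 10L, min_split = 10L, min_leaf = 5L,
                    prune = TRUE, validation_frac = 0.25, seed = 1L) {
  d <- prepare_xy(data, target, features)
  y <- as.numeric(d$y)
  classes <- sort(as.numeric(classes))
  trees <- lapply(classes[-length(classes)], function(k) {
    yb <- ifelse(y > k, "gt", "le")
    df <- d$x
    df$.target <- yb
    if (length(unique(yb)) < 2) {
      # one-class sub-problem: constant estimate
      structure(list(constant = mean(y > k)), class = "als_cpt_constant")
    } else {
      fit_tree_impl(df, ".target", d$features, "class", c("gt", "le"),
                    max_depth, min_split, min_leaf, prune, validation_frac,
                    seed)
    }
  })
  structure(list(trees = trees, classes = classes, features = d$features),
            class = "als_cpt")
}

#' @export
predict.als_cpt <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- tibble::as_tibble(newdata)
  n <- nrow(newdata)
  K <- length(object$classes)
  # P(y > k) for each threshold
  pgt <- vapply(object$trees, function(tr) {
    if (inherits(tr, "als_cpt_constant")) rep(tr$constant, n)
    else predict(tr, newdata, type = "prob")[, "gt"]
  }, numeric(n))
  pgt <- matrix(pgt, nrow = n)
  # enforce a non-increasing cumulative sequence before differencing
  for (j in seq_len(ncol(pgt))[-1]) {
    pgt[, j] <- pmin(pgt[, j], pgt[, j - 1])
  }
  probs <- cbind(1 - pgt[, 1],
                 if (K > 2) pgt[, -ncol(pgt), drop = FALSE] -
                   pgt[, -1, drop = FALSE],
                 pgt[, ncol(pgt)])
  probs[probs < 0] <- 0
  probs <- probs / pmax(rowSums(probs), 1e-12)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.als_cpt <- function(x, ...) {
  cat("<als_cpt> ", length(x$trees), " cumulative binary trees\n", sep = "")
  invisible(x)
}
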