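# Discrete Bayesian-network classifier: structure learning by risk
# minimization by cross-validation (RMCV) — greedy hill climbing over
# single-edge moves from the empty graph, each candidate scored by the
# internally cross-validated prediction quality of the designated class
# node — plus Markov-blanket extraction and exact inference.

# edges: tibble(from, to); may have zero rows
empty_edges <- function() tibble::tibble(from = character(), to = character())

edge_parents <- function(edges, node) edges$from[edges$to == node]
edge_children <- function(edges, node) edges$to[edges$from == node]

edges_acyclic <- function(edges, nodes) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(edges$to, levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  remaining <- nodes
  repeat {
    ready <- remaining[indeg[remaining] == 0]
    if (length(ready) == 0) return(length(remaining) == 0)
    remaining <- setdiff(remaining, ready)
    for (r in ready) {
      ch <- edges$to[edges$from == r & edges$to %in% remaining]
      indeg[ch] <- indeg[ch] - 1L
    }
  }
}

#' Markov blanket of the class node
#'
#' Parents, children, and children's co-parents of the class node.
#'
#' @param model An `als_bn`, or a tibble of edges (`from`, `to`) with
#'   `class_node` given.
#' @param class_node Class node name (taken from the model if omitted).
#' @return Character vector of blanket variable names (never containing
#'   the class node itself).
#' @export
markov_blanket <- function(model, class_node = NULL) {
  if (inherits(model, "als_bn")) {
    edges <- model$edges
    class_node <- class_node %||% model$class_node
  } else {
    edges <- tibble::as_tibble(model)
  }
  if (is.null(class_node)) abort_config("class_node must be supplied")
  parents <- edge_parents(edges, class_node)
  children <- edge_children(edges, class_node)
  coparents <- unlist(lapply(children, function(ch) edge_parents(edges, ch)))
  setdiff(unique(c(parents, children, coparents)), class_node)
}

# CPT estimation with Laplace smoothing; arrays dimensioned parents x node
fit_cpts <- function(data, edges, levels, alpha = 1) {
  lapply(stats::setNames(names(levels), names(levels)), function(node) {
    pars <- edge_parents(edges, node)
    f <- lapply(c(pars, node), function(v) factor(data[[v]], levels = levels[[v]]))
    tab <- table(f) + alpha
    nd <- length(dim(tab))
    den <- if (nd == 1) sum(tab) else
      array(rep(apply(tab, seq_len(nd - 1), sum),
                times = dim(tab)[nd]), dim = dim(tab))
    cpt <- tab / den
    attr(cpt, "parents") <- pars
    cpt
  })
}

# log-probability of node's observed value for each candidate class value.
# `assign` is a named list of integer level-index vectors (length n) for
# every variable; `class_idx` overrides the class node's index.
cpt_log_lookup <- function(cpt, levels, assign, node, class_node, class_idx) {
  pars <- attr(cpt, "parents")
  vars <- c(pars, node)
  dims <- vapply(vars, function(v) length(levels[[v]]), integer(1))
  idx_of <- function(v) {
    if (v == class_node) class_idx else assign[[v]]
  }
  lin <- idx_of(vars[1])
  stride <- dims[1]
  if (length(vars) > 1) {
    for (j in 2:length(vars)) {
      lin <- lin + (idx_of(vars[j]) - 1L) * stride
      stride <- stride * dims[j]
    }
  }
  log(as.numeric(cpt)[lin])
}

# vectorized posterior over class values when all other variables are
# observed: only the class node's own CPT and its children's CPTs involve
# the class, so the posterior is the normalised product of those factors
predict_bn_scores <- function(data, edges, cpts, levels, class_node) {
  n <- nrow(data)
  K <- length(levels[[class_node]])
  assign <- lapply(stats::setNames(names(levels), names(levels)), function(v) {
    match(as.character(data[[v]]), levels[[v]])
  })
  children <- edge_children(edges, class_node)
  scores <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ck <- rep(k, n)
    s <- cpt_log_lookup(cpts[[class_node]], levels, assign, class_node,
                        class_node, ck)
    for (ch in children) {
      s <- s + cpt_log_lookup(cpts[[ch]], levels, assign, ch, class_node, ck)
    }
    scores[, k] <- s
  }
  p <- exp(scores - apply(scores, 1, max))
  p / rowSums(p)
}

#' Learn a Bayesian-network classifier by cross-validated risk
#'
#' Greedy hill climbing over single-edge additions, deletions and
#' reversals, starting from the empty graph.  Each candidate structure is
#' scored by `cv`-fold cross-validated prediction of the class node (by
#' default classification accuracy; optionally negative MAE for ordinal
#' classes); a move is accepted only if it strictly improves the score
#' (ties break toward fewer edges, so edges irrelevant to the class node's
#' Markov-blanket factorization are never added).  Conditional probability
#' tables are estimated with Laplace smoothing.
#'
#' @param data Data frame of discrete (character/factor) variables.
#' @param class_node Name of the class variable.
#' @param max_parents Maximal in-degree (default 4).
#' @param cv Internal scoring folds (default 5, class-stratified).
#' @param score `"accuracy"` (default) or `"mae"` (requires numeric-coded
#'   class levels).
#' @param alpha Laplace smoothing count (default 1).
#' @param max_iter Cap on hill-climbing iterations.
#' @param seed Seed for the internal folds.
#' @return An `als_bn`: `nodes`, `levels`, `edges`, `cpts` (fit on all
#'   data), `class_node`, `score`, `trace`.
#' @export
rmcv_learn <- function(data, class_node, max_parents = 4L, cv = 5L,
                       score = c("accuracy", "mae"), alpha = 1,
                       max_iter = 100L, seed = 1L) {
  score <- match.arg(score)
  data <- tibble::as_tibble(data)
  data <- data[, setdiff(names(data), "patient_id")]
  data <- dplyr::mutate(data, dplyr::across(dplyr::everything(), as.character))
  if (!class_node %in% names(data)) abort_config("class_node not in data")
  nodes <- names(data)
  levels <- lapply(data, function(v) sort(unique(v)))
  if (any(lengths(levels) < 1)) abort_config("empty variable")
  class_values <- suppressWarnings(as.numeric(levels[[class_node]]))
  if (score == "mae" && anyNA(class_values)) {
    abort_config("mae scoring requires numeric class levels")
  }

  fold <- make_stratified_folds(data[[class_node]], cv, seed)
  y_obs <- data[[class_node]]

  score_edges <- function(edges) {
    correct <- 0
    err <- 0
    for (f in seq_len(cv)) {
      test <- fold == f
      cpts <- fit_cpts(data[!test, , drop = FALSE], edges, levels, alpha)
      p <- predict_bn_scores(data[test, , drop = FALSE], edges, cpts,
                             levels, class_node)
      if (score == "accuracy") {
        pred <- levels[[class_node]][max.col(p, "first")]
        correct <- correct + sum(pred == y_obs[test])
      } else {
        pred <- class_values[max.col(t(apply(p, 1, cumsum)) >= 0.5, "first")]
        err <- err + sum(abs(pred - as.numeric(y_obs[test])))
      }
    }
    if (score == "accuracy") correct / nrow(data) else -err / nrow(data)
  }

  # class-relevant signature: the factorization pieces that can change the
  # class posterior — moves leaving it unchanged cannot change the score
  signature <- function(edges) {
    ch <- sort(edge_children(edges, class_node))
    fams <- lapply(c(class_node, ch), function(v) {
      c(v, sort(edge_parents(edges, v)))
    })
    paste(vapply(fams, paste, "", collapse = ","), collapse = ";")
  }

  edges <- empty_edges()
  best_score <- score_edges(edges)
  trace <- tibble::tibble(iteration = 0L, move = "start", score = best_score,
                          n_edges = 0L)

  for (it in seq_len(max_iter)) {
    cur_sig <- signature(edges)
    present <- paste(edges$from, edges$to)
    cands <- list()
    for (u in nodes) for (v in nodes) {
      if (u == v) next
      key <- paste(u, v)
      if (!key %in% present) {
        e2 <- dplyr::bind_rows(edges, tibble::tibble(from = u, to = v))
        if (length(edge_parents(e2, v)) <= max_parents &&
            edges_acyclic(e2, nodes)) {
          cands[[length(cands) + 1]] <- list(edges = e2,
                                             move = paste("add", u, "->", v))
        }
      }
    }
    for (j in seq_len(nrow(edges))) {
      e2 <- edges[-j, , drop = FALSE]
      cands[[length(cands) + 1]] <- list(
        edges = e2, move = paste("delete", edges$from[j], "->", edges$to[j]))
      e3 <- dplyr::bind_rows(e2, tibble::tibble(from = edges$to[j],
                                                to = edges$from[j]))
      if (length(edge_parents(e3, edges$from[j])) <= max_parents &&
          edges_acyclic(e3, nodes)) {
        cands[[length(cands) + 1]] <- list(
          edges = e3, move = paste("reverse", edges$from[j], "->", edges$to[j]))
      }
    }
    best_cand <- NULL
    best_cand_score <- -Inf
    for (cand in cands) {
      if (signature(cand$edges) == cur_sig) next  # score provably unchanged
      s <- score_edges(cand$edges)
      if (is.null(best_cand) || s > best_cand_score + 1e-12 ||
          (abs(s - best_cand_score) <= 1e-12 &&
             nrow(cand$edges) < nrow(best_cand$edges))) {
        best_cand <- cand
        best_cand_score <- s
      }
    }
    accept <- !is.null(best_cand) &&
      (best_cand_score > best_score + 1e-12 ||
         (abs(best_cand_score - best_score) <= 1e-12 &&
            nrow(best_cand$edges) < nrow(edges)))
    if (!accept) break
    edges <- best_cand$edges
    best_score <- best_cand_score
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      iteration = it, move = best_cand$move, score = best_score,
      n_edges = nrow(edges)))
  }

  cpts <- fit_cpts(data, edges, levels, alpha)
  structure(list(nodes = nodes, levels = levels, edges = edges, cpts = cpts,
                 class_node = class_node, score = best_score,
                 score_type = score, alpha = alpha, trace = trace),
            class = "als_bn")
}

#' Construct an `als_bn` from known structure and data
#'
#' Fits smoothed CPTs for a user-specified edge list; useful for planted
#' structures and for restricting a learned model to its Markov blanket.
#'
#' @param data Discrete data frame. @param edges Tibble `from`, `to`.
#' @param class_node Class variable. @param alpha Laplace count.
#' @return An `als_bn`.
#' @export
bn_from_structure <- function(data, edges, class_node, alpha = 1) {
  data <- tibble::as_tibble(data)
  data <- data[, setdiff(names(data), "patient_id")]
  data <- dplyr::mutate(data, dplyr::across(dplyr::everything(), as.character))
  edges <- tibble::as_tibble(edges)
  nodes <- names(data)
  if (!edges_acyclic(edges, nodes)) abort_config("edge list is cyclic")
  levels <- lapply(data, function(v) sort(unique(v)))
  structure(list(nodes = nodes, levels = levels, edges = edges,
                 cpts = fit_cpts(data, edges, levels, alpha),
                 class_node = class_node, score = NA_real_,
                 score_type = NA_character_, alpha = alpha,
                 trace = NULL),
            class = "als_bn")
}

#' @export
print.als_bn <- function(x, ...) {
  cat("<als_bn> class node ", x$class_node, "; ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges", sep = "")
  if (!is.na(x$score)) cat("; CV ", x$score_type, " ", signif(x$score, 4),
                           sep = "")
  cat("\nMarkov blanket: ",
      paste(markov_blanket(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.als_bn <- function(x, ...) x$edges

#' @export
glance.als_bn <- function(x, ...) {
  tibble::tibble(nodes = length(x$nodes), edges = nrow(x$edges),
                 mb_size = length(markov_blanket(x)),
                 cv_score = x$score, score_type = x$score_type)
}

#' Exact class posterior given (possibly partial) evidence
#'
#' Computes `P(class | evidence)` by exact enumeration: unobserved barren
#' variables (childless non-class nodes) are pruned — they sum out of the
#' joint — and the remaining unobserved variables are enumerated jointly
#' with the class over the product of conditional probability tables.
#' Missing evidence is therefore marginalised exactly.
#'
#' @param model An `als_bn`.
#' @param evidence One-row data frame or named list/vector of observed
#'   values; variables absent or `NA` are treated as unobserved.
#' @return Named numeric vector: the posterior over the class levels.
#' @export
bn_predict <- function(model, evidence) {
  ev <- as.list(evidence)
  ev <- ev[!vapply(ev, function(v) is.null(v) || is.na(v), logical(1))]
  ev <- ev[intersect(names(ev), model$nodes)]
  class_node <- model$class_node
  ev[[class_node]] <- NULL

  nodes <- model$nodes
  unobs <- setdiff(nodes, c(names(ev), class_node))
  # barren pruning: an unobserved non-class leaf contributes a factor that
  # sums to one
  repeat {
    barren <- unobs[vapply(unobs, function(u) {
      length(intersect(edge_children(model$edges, u), nodes)) == 0
    }, logical(1))]
    if (length(barren) == 0) break
    nodes <- setdiff(nodes, barren)
    unobs <- setdiff(unobs, barren)
  }
  enum_vars <- c(class_node, unobs)
  grids <- lapply(model$levels[enum_vars], seq_along)
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  assign <- lapply(stats::setNames(nodes, nodes), function(v) {
    if (v %in% enum_vars) as.integer(grid[[v]])
    else rep(match(as.character(ev[[v]]), model$levels[[v]]), n)
  })
  logp <- rep(0, n)
  for (v in nodes) {
    logp <- logp + cpt_log_lookup(model$cpts[[v]], model$levels, assign, v,
                                  class_node, assign[[class_node]])
  }
  w <- exp(logp - max(logp))
  post <- tapply(w, grid[[class_node]], sum)
  out <- numeric(length(model$levels[[class_node]]))
  out[as.integer(names(post))] <- post
  out <- out / sum(out)
  stats::setNames(out, model$levels[[class_node]])
}

#' Predicted class for each row of a table with full evidence
#'
#' Fast path used by the structure search: every non-class variable is
#' assumed observed, so the posterior involves only the class node's own
#' CPT and its children's CPTs.
#'
#' @param object An `als_bn`. @param data Data frame of discrete values.
#' @param type `"class"` or `"prob"`. @param ... Unused.
#' @return Class vector or probability matrix over class levels.
#' @export
predict.als_bn <- function(object, data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  data <- tibble::as_tibble(data)
  data <- dplyr::mutate(data, dplyr::across(dplyr::everything(), as.character))
  p <- predict_bn_scores(data, object$edges, object$cpts, object$levels,
                         object$class_node)
  colnames(p) <- object$levels[[object$class_node]]
  if (type == "prob") p else colnames(p)[max.col(p, "first")]
}

#' Restrict a model to its class Markov blanket
#'
#' Keeps the class node and its blanket, with the induced edges; CPTs are
#' refit from the supplied data (needed because removed co-parent paths may
#' have carried parents of blanket nodes).
#'
#' @param model An `als_bn`. @param data The training data.
#' @return An `als_bn` over the blanket variables.
#' @export
bn_keep_mb <- function(model, data) {
  keep <- c(model$class_node, markov_blanket(model))
  edges <- model$edges[model$edges$from %in% keep & model$edges$to %in% keep, ]
  data <- tibble::as_tibble(data)[, intersect(keep, names(tibble::as_tibble(data)))]
  bn_from_structure(data, edges, model$class_node, model$alpha)
}

#' Serialize a network to Graphviz DOT
#'
#' @param model An `als_bn`. @param mb_only Show only the class node and
#'   its Markov blanket. @param file Optional output path.
#' @return DOT text (invisibly when written to file).
#' @export
bn_to_dot <- function(model, mb_only = FALSE, file = NULL) {
  keep <- if (mb_only) c(model$class_node, markov_blanket(model)) else
    model$nodes
  edges <- model$edges[model$edges$from %in% keep & model$edges$to %in% keep, ]
  lines <- c("digraph bn {",
             paste0("  \"", model$class_node,
                    "\" [shape=doublecircle];"),
             paste0("  \"", setdiff(keep, model$class_node), "\";"),
             paste0("  \"", edges$from, "\" -> \"", edges$to, "\";"),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
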