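# Independent oracles used across the suite.  Each is written from the
# defining formula, by enumeration or brute force, independently of the
# package's implementation paths.

# first-order sensitivity from a fully specified joint probability table:
# rows = predictor values, cols = numeric target values
si_from_joint <- function(P, y_values) {
  P <- P / sum(P)
  py <- colSums(P)
  mu <- sum(py * y_values)
  vy <- sum(py * (y_values - mu)^2)
  px <- rowSums(P)
  cm <- as.numeric((P %*% y_values) / px)
  sum(px * (cm - mu)^2) / vy
}

# empirical Si by direct grouping (no binning; predictor already discrete)
si_empirical <- function(x, y) {
  tab <- table(x, y)
  si_from_joint(unclass(tab), as.numeric(colnames(tab)))
}

# proportional-odds log-likelihood for one numeric predictor, maximized
# numerically; returns cumulative intercepts (zeta) and slope
polr_oracle <- function(x, y) {
  lev <- sort(unique(y))
  K <- length(lev)
  yi <- match(y, lev)
  nll <- function(par) {
    zeta <- cumsum(c(par[1], exp(par[2:(K - 1)])))
    beta <- par[K]
    hi <- c(zeta, Inf)[yi] - beta * x
    lo <- c(-Inf, zeta)[yi] - beta * x
    -sum(log(plogis(hi) - plogis(lo)))
  }
  start <- c(qlogis(cumsum(table(yi) / length(yi)))[1], rep(0, K - 2), 0)
  fit <- optim(start, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  zeta <- cumsum(c(fit$par[1], exp(fit$par[2:(K - 1)])))
  list(zeta = zeta, beta = fit$par[K], value = fit$value)
}

# Markov blanket recomputed from an adjacency matrix
mb_oracle <- function(edges, nodes, class_node) {
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) A[cbind(edges$from, edges$to)] <- TRUE
  parents <- nodes[A[, class_node]]
  children <- nodes[A[class_node, ]]
  cop <- character(0)
  for (ch in children) cop <- c(cop, nodes[A[, ch]])
  setdiff(unique(c(parents, children, cop)), class_node)
}

# exhaustive best split for 1-D ordinal data under summed |y - median|
best_mae_split_oracle <- function(x, y) {
  xs <- sort(unique(x))
  cost_of <- function(v) {
    if (length(v) == 0) return(0)
    m <- median(v)
    cands <- c(floor(m), ceiling(m))
    min(vapply(cands, function(c) sum(abs(v - c)), numeric(1)))
  }
  best <- NULL
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    cost <- cost_of(y[x <= thr]) + cost_of(y[x > thr])
    if (is.null(best) || cost < best$cost) best <- list(threshold = thr,
                                                        cost = cost)
  }
  best
}

# exact posterior over the class by enumerating the full joint of an
# als_bn model
bn_posterior_oracle <- function(model, evidence) {
  lv <- model$levels
  grid <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- names(lv)
  p <- rep(1, nrow(grid))
  for (v in model$nodes) {
    cpt <- model$cpts[[v]]
    pars <- attr(cpt, "parents")
    idx <- match(grid[[v]], lv[[v]])
    lin <- idx * 0
    stride <- 1
    for (u in c(pars, v)) {
      iu <- match(grid[[u]], lv[[u]])
      lin <- lin + (iu - 1) * stride
      stride <- stride * length(lv[[u]])
    }
    p <- p * as.numeric(cpt)[lin + 1]
  }
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) {
    if (v %in% names(grid) && !is.na(evidence[[v]])) {
      keep <- keep & grid[[v]] == as.character(evidence[[v]])
    }
  }
  post <- tapply(p[keep], grid[[model$class_node]][keep], sum)
  out <- setNames(numeric(length(lv[[model$class_node]])),
                  lv[[model$class_node]])
  out[names(post)] <- post
  out / sum(out)
}

# a random DAG over the given nodes (edges respect a random order)
random_dag <- function(nodes, p = 0.3, seed = 1) {
  set.seed(seed)
  ord <- sample(nodes)
  from <- character(0); to <- character(0)
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (i < j && runif(1) < p) {
      from <- c(from, ord[i]); to <- c(to, ord[j])
    }
  }
  tibble::tibble(from = from, to = to)
}

# small planted v-structure network: A -> Class <- B, Class -> C, plus an
# independent noise node D
planted_mb_network <- function() {
  list(
    bn_node("A", c("a0", "a1"), cpt = c(0.55, 0.45)),
    bn_node("B", c("b0", "b1"), cpt = c(0.4, 0.6)),
    bn_node("Class", c("c0", "c1", "c2"), parents = c("A", "B"),
            cpt = array(c(
              # P(Class | A, B): rows over (A,B) combos, last dim Class
              0.75, 0.35, 0.45, 0.05,
              0.15, 0.40, 0.35, 0.25,
              0.10, 0.25, 0.20, 0.70
            ), dim = c(2, 2, 3))),
    bn_node("C", c("x", "y"), parents = "Class",
            cpt = array(c(0.85, 0.5, 0.15,
                          0.15, 0.5, 0.85), dim = c(3, 2))),
    bn_node("D", c("d0", "d1"), cpt = c(0.5, 0.5))
  )
}

# integer in 0..4 minimising the summed absolute deviation
median_int <- function(v) {
  costs <- vapply(0:4, function(c) sum(abs(v - c)), numeric(1))
  (0:4)[which.min(costs)]
}
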