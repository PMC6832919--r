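# Ancestral sampling from a fully specified discrete Bayesian network,
# used to plant ground-truth structures for structure-recovery tests.

#' Specify one node of a discrete Bayesian network
#'
#' @param name Node name.
#' @param levels Character vector of the node's levels.
#' @param parents Character vector of parent node names (default none).
#' @param cpt For a root node, a numeric vector of probabilities over
#'   `levels`.  For a node with parents, an array whose first dimensions run
#'   over the parents' levels (in `parents` order) and whose last dimension
#'   runs over the node's own levels; every slice over the last dimension
#'   must sum to 1.
#' @return A list of class `bn_node_spec`.
#' @export
bn_node <- function(name, levels, parents = character(), cpt) {
  levels <- as.character(levels)
  cpt <- as.array(cpt)
  if (length(parents) == 0) {
    if (length(cpt) != length(levels)) {
      abort_config(paste0("cpt for root node ", name, " must have ",
                          length(levels), " entries"))
    }
    if (abs(sum(cpt) - 1) > 1e-8 || any(cpt < 0)) {
      abort_config(paste0("cpt for ", name, " is not a distribution"))
    }
  } else {
    nd <- length(dim(cpt))
    if (nd != length(parents) + 1 || dim(cpt)[nd] != length(levels)) {
      abort_config(paste0("cpt for ", name,
                          " must have one dimension per parent plus the node"))
    }
    sums <- apply(cpt, seq_len(nd - 1), sum)
    if (any(abs(sums - 1) > 1e-8) || any(cpt < 0)) {
      abort_config(paste0("cpt rows for ", name, " must each sum to 1"))
    }
  }
  structure(list(name = name, levels = levels,
                 parents = as.character(parents), cpt = cpt),
            class = "bn_node_spec")
}

# Kahn topological sort; errors on cycles
bn_topological_order <- function(nodes) {
  names(nodes) <- purrr::map_chr(nodes, "name")
  indeg <- purrr::map_int(nodes, ~ length(.x$parents))
  order <- character(0)
  remaining <- names(nodes)
  while (length(remaining) > 0) {
    ready <- remaining[indeg[remaining] == 0]
    if (length(ready) == 0) {
      rlang::abort("Bayesian-network specification contains a cycle",
                   class = "alsord_config_error")
    }
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
    for (nm in remaining) {
      indeg[nm] <- length(setdiff(nodes[[nm]]$parents, order))
    }
  }
  missing_par <- unlist(lapply(nodes, function(nd) setdiff(nd$parents, names(nodes))))
  if (length(missing_par) > 0) {
    abort_config(paste("parent not in network:", paste(missing_par, collapse = ", ")))
  }
  order
}

#' Sample records from a specified Bayesian network
#'
#' Draws `n` i.i.d. records by ancestral sampling: nodes are visited in
#' topological order and each is sampled from its conditional probability
#' table given its already-sampled parents.
#'
#' @param nodes List of [bn_node()] specifications (acyclic).
#' @param n Number of records.
#' @param seed Integer seed.
#' @return A tibble with one character column per node.
#' @export
sample_bn <- function(nodes, n, seed = 1L) {
  names(nodes) <- purrr::map_chr(nodes, "name")
  ord <- bn_topological_order(nodes)
  with_seed(seed, {
    out <- vector("list", length(nodes))
    names(out) <- names(nodes)
    for (nm in ord) {
      nd <- nodes[[nm]]
      k <- length(nd$levels)
      if (length(nd$parents) == 0) {
        idx <- sample.int(k, n, replace = TRUE, prob = as.numeric(nd$cpt))
      } else {
        # index the flattened CPT: parent configuration selects the row
        pidx <- lapply(nd$parents, function(p) {
          match(out[[p]], nodes[[p]]$levels)
        })
        pdims <- purrr::map_int(nd$parents, ~ length(nodes[[.x]]$levels))
        row <- pidx[[1]]
        mult <- pdims[1]
        if (length(pidx) > 1) {
          for (j in 2:length(pidx)) {
            row <- row + (pidx[[j]] - 1L) * mult
            mult <- mult * pdims[j]
          }
        }
        pm <- matrix(nd$cpt, nrow = mult, ncol = k)
        u <- runif(n)
        cum <- t(apply(pm, 1, cumsum))
        idx <- integer(n)
        for (j in seq_len(k)) {
          sel <- idx == 0L & u <= cum[row, j] + 1e-12
          idx[sel] <- j
        }
        idx[idx == 0L] <- k
      }
      out[[nm]] <- nd$levels[idx]
    }
    tibble::as_tibble(out[names(nodes)])
  })
}
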