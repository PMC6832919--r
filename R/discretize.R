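# Supervised discretization by the entropy / minimum-description-length
# criterion: recursive binary cuts that minimise class entropy, accepted
# only when the information gain exceeds the MDL coding cost, so label-
# independent variables receive no cuts at all.

entropy_labels <- function(y) {
  entropy_counts(as.numeric(table(y)))
}

# best single cut on sorted values; returns NULL or list(pos, gain, delta)
best_cut <- function(v, y) {
  n <- length(v)
  ylev <- unique(y)
  k <- length(ylev)
  if (n < 2 || k < 2) return(NULL)
  yi <- match(y, ylev)
  M <- matrix(0L, n, k)
  M[cbind(seq_len(n), yi)] <- 1L
  C <- apply(M, 2, cumsum)
  bnd <- which(diff(v) > 0)
  if (length(bnd) == 0) return(NULL)
  tot <- C[n, ]
  hl <- apply(C[bnd, , drop = FALSE], 1, entropy_counts)
  hr <- apply(matrix(tot, length(bnd), k, byrow = TRUE) -
                C[bnd, , drop = FALSE], 1, entropy_counts)
  went <- (bnd * hl + (n - bnd) * hr) / n
  j <- which.min(went)
  pos <- bnd[j]
  hs <- entropy_counts(tot)
  gain <- hs - went[j]
  k1 <- sum(C[pos, ] > 0)
  k2 <- sum(tot - C[pos, ] > 0)
  delta <- log2(3^k - 2) - (k * hs - k1 * hl[j] - k2 * hr[j])
  list(pos = pos, gain = gain,
       threshold = (v[pos] + v[pos + 1]) / 2,
       accept = gain > (log2(n - 1) + delta) / n)
}

mdl_cuts_rec <- function(v, y) {
  bc <- best_cut(v, y)
  if (is.null(bc) || !bc$accept) return(numeric(0))
  left <- seq_len(bc$pos)
  c(mdl_cuts_rec(v[left], y[left]),
    bc$threshold,
    mdl_cuts_rec(v[-left], y[-left]))
}

#' MDL supervised discretization of one variable
#'
#' Recursive binary entropy-minimising cuts accepted under the Fayyad–Irani
#' MDL stopping rule.  Variables carrying no class information (or constant
#' values) receive an empty scheme.
#'
#' @param values Numeric vector.
#' @param labels Class labels (>= 2 classes for any cut to be considered).
#' @return A list of class `als_discretization`: `cuts` (strictly
#'   increasing thresholds, possibly empty) and `levels` (labels of the
#'   resulting intervals).
#' @export
mdl_discretize <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  v <- values[ok]; y <- labels[ok]
  o <- order(v)
  cuts <- sort(unique(mdl_cuts_rec(v[o], y[o])))
  lv <- if (length(cuts) == 0) "all" else
    levels(cut(0, breaks = c(-Inf, cuts, Inf)))
  structure(list(cuts = cuts, levels = lv), class = "als_discretization")
}

#' @export
print.als_discretization <- function(x, ...) {
  if (length(x$cuts) == 0) cat("<als_discretization> no cuts\n")
  else cat("<als_discretization> cuts at ",
           paste(signif(x$cuts, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Apply a discretization scheme
#'
#' @param scheme An [mdl_discretize()] result (or a numeric vector of cut
#'   points).
#' @param values Numeric vector to discretize.
#' @return Character vector of interval levels; a single level `"all"`
#'   when the scheme has no cuts.
#' @export
apply_discretization <- function(scheme, values) {
  cuts <- if (inherits(scheme, "als_discretization")) scheme$cuts else
    sort(scheme)
  if (length(cuts) == 0) return(rep("all", length(values)))
  as.character(cut(values, breaks = c(-Inf, cuts, Inf)))
}

#' MDL-discretize every continuous column of a table against a target
#'
#' Numeric columns are discretized supervised by the target; columns whose
#' scheme is empty carry no class information under MDL and are dropped
#' (they would enter a Bayesian network as uninformative constants).
#' Non-numeric columns pass through unchanged.
#'
#' @param data Data frame. @param target Target column name.
#' @param columns Columns to consider; defaults to all numeric feature
#'   columns.
#' @param keep_empty Keep (as the single level `"all"`) rather than drop
#'   columns with empty schemes.
#' @return List: `data` (tibble of character columns plus the target),
#'   `schemes` (named list), `dropped` (character).
#' @export
discretize_table <- function(data, target = "target", columns = NULL,
                             keep_empty = FALSE) {
  data <- tibble::as_tibble(data)
  if (is.null(columns)) {
    columns <- setdiff(names(data), c(target, "patient_id"))
  }
  y <- data[[target]]
  schemes <- list()
  dropped <- character(0)
  out <- data[, intersect(c("patient_id", target), names(data))]
  for (cl in columns) {
    v <- data[[cl]]
    if (!is.numeric(v)) {
      out[[cl]] <- as.character(v)
      next
    }
    sc <- mdl_discretize(v, y)
    schemes[[cl]] <- sc
    if (length(sc$cuts) == 0 && !keep_empty) {
      dropped <- c(dropped, cl)
    } else {
      out[[cl]] <- apply_discretization(sc, v)
    }
  }
  list(data = out, schemes = schemes, dropped = dropped)
}
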