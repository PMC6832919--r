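# Functional grouping of the ten ALSFRS items: pairwise correlation,
# average-linkage agglomeration on distance 1 - correlation, tree cut into
# a small number of higher-level functional groups.

#' Cluster the ALSFRS items into functional groups
#'
#' Computes the pairwise correlation matrix of the ten last-visit ALSFRS
#' items (Spearman by default — the items are ordinal), converts it to the
#' distance `1 - correlation`, agglomerates by average linkage, and cuts
#' the tree into `n_groups` groups.  Items with zero variance have no
#' defined correlation and are isolated into singleton groups with a
#' warning.
#'
#' @param data Data frame with one column per item (e.g. the
#'   `alsfrs_<item>_last` columns of an `als_dataset`, or plain item-named
#'   columns). Columns are matched by stripping `alsfrs_` / `_last`
#'   decorations.
#' @param n_groups Number of groups to cut (default 5, the conventional
#'   partition; 4 merges full-body into the limb groups).
#' @param method Correlation type, `"spearman"` (default) or `"pearson"`.
#' @return A list of class `als_grouping`: `correlation` (10x10 matrix),
#'   `linkage` (`hclust` tree), `groups` (named list of item vectors),
#'   `membership` (named integer vector), `n_groups`.
#' @export
cluster_items <- function(data, n_groups = 5L,
                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  items <- alsfrs_items()
  nm <- sub("^alsfrs_", "", sub("_last$", "", names(data)))
  cols <- match(items, nm)
  if (anyNA(cols)) {
    found <- items[!is.na(cols)]
    abort_config(paste("missing ALSFRS item columns:",
                       paste(setdiff(items, found), collapse = ", ")))
  }
  x <- as.matrix(data[, cols])
  colnames(x) <- items
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) abort_config("need at least 3 complete ALSFRS vectors")

  const <- apply(x, 2, function(v) var(v) == 0)
  if (any(const)) {
    rlang::warn(paste("constant item(s) isolated into singleton groups:",
                      paste(items[const], collapse = ", ")))
  }
  live <- items[!const]
  cm <- matrix(NA_real_, 10, 10, dimnames = list(items, items))
  diag(cm) <- 1
  if (length(live) >= 2) {
    cm[live, live] <- cor(x[, live, drop = FALSE], method = method)
  }

  k_live <- max(min(n_groups - sum(const), length(live)), 1)
  if (length(live) >= 2) {
    d <- as.dist(1 - cm[live, live])
    hc <- hclust(d, method = "average")
    memb_live <- cutree(hc, k = k_live)
  } else {
    hc <- NULL
    memb_live <- stats::setNames(rep(1L, length(live)), live)
  }
  membership <- integer(10)
  names(membership) <- items
  membership[live] <- memb_live
  if (any(const)) {
    membership[items[const]] <- max(memb_live, 0) + seq_len(sum(const))
  }
  groups <- split(names(membership), membership)
  names(groups) <- paste0("group_", seq_along(groups))
  structure(list(correlation = cm, linkage = hc, groups = groups,
                 membership = membership, n_groups = length(groups),
                 method = method),
            class = "als_grouping")
}

#' @export
print.als_grouping <- function(x, ...) {
  cat("<als_grouping> ", x$n_groups, " groups (", x$method, " correlation)\n",
      sep = "")
  for (g in names(x$groups)) {
    cat("  ", g, ": ", paste(x$groups[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.als_grouping <- function(x, ...) {
  tibble::tibble(item = names(x$membership),
                 group = paste0("group_", x$membership))
}

#' Export the item dendrogram as a Newick string
#'
#' Merge heights become branch lengths via the standard `hclust` to
#' phylogeny conversion.
#'
#' @param grouping An `als_grouping`.
#' @param file Optional path to write to.
#' @return The Newick string, invisibly when written to a file.
#' @export
grouping_newick <- function(grouping, file = NULL) {
  if (is.null(grouping$linkage)) abort_config("grouping has no linkage tree")
  phy <- ape::as.phylo(grouping$linkage)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Do two partitions of the same items agree exactly?
#'
#' Partition equality up to group relabelling; used to check recovery of a
#' planted block structure.
#'
#' @param a,b Named membership vectors or lists of item groups.
#' @return Logical.
#' @export
same_partition <- function(a, b) {
  to_memb <- function(p) {
    if (is.list(p)) {
      stats::setNames(rep(seq_along(p), lengths(p)), unlist(p))
    } else p
  }
  ma <- to_memb(a); mb <- to_memb(b)
  items <- sort(names(ma))
  if (!identical(items, sort(names(mb)))) return(FALSE)
  ma <- ma[items]; mb <- mb[items]
  length(unique(paste(ma, mb))) == length(unique(ma)) &&
    length(unique(ma)) == length(unique(mb))
}
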