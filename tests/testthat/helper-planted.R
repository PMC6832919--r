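# ten ordinal items with a planted block correlation structure matching
# the conventional five functional groups
planted_block_items <- function(n, seed, within = 0.9, between = 0.1) {
  groups <- alsfrs_groups()
  items <- alsfrs_items()
  R <- matrix(between, 10, 10, dimnames = list(items, items))
  for (g in names(groups)) {
    R[groups[[g]], groups[[g]]] <- within
  }
  diag(R) <- 1
  L <- chol(R)
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * 10), n, 10) %*% L
    x <- apply(z, 2, function(v) {
      as.integer(cut(v, breaks = quantile(v, probs = seq(0, 1, 0.2)),
                     include.lowest = TRUE)) - 1L
    })
    colnames(x) <- items
    tibble::as_tibble(x)
  })
}
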