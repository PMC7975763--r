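# Independent brute-force oracles and fixture generators used across tests.
# These deliberately avoid the package's own algorithms: Dollo is checked by
# exhaustive enumeration of internal presence assignments, Wagner by
# exhaustive enumeration of ancestral state vectors, the hypergeometric tail
# by direct binomial-coefficient arithmetic, and BH by an explicit step-up
# loop.

# random rooted binary tree topology with n uniquely labeled leaves
random_species_tree <- function(n_leaves) {
  phy <- ape::rtree(n_leaves, rooted = TRUE,
                    tip.label = paste0("sp", seq_len(n_leaves)))
  phy$edge.length <- NULL
  parse_species_tree(ape::write.tree(phy))
}

# Dollo oracle: enumerate every single-gain presence assignment on internal
# nodes consistent with the leaf profile; return min losses and the gain node
# of the optimum.
dollo_brute <- function(presence, tree) {
  nodes <- tree$preorder
  internal <- nodes[!nodes %in% tree$leaves]
  leaves <- tree$leaves
  parent <- tree$parent
  if (!any(presence[leaves])) return(list(n_losses = 0L, gain_node = NA_character_))

  best <- Inf
  best_gain <- NULL
  n_int <- length(internal)
  for (mask in 0:(2^n_int - 1)) {
    pres <- setNames(c(as.logical(bitwAnd(mask, 2^(seq_len(n_int) - 1L))),
                       unname(presence[leaves])),
                     c(internal, leaves))
    present_set <- names(pres)[pres]
    # valid single-gain config: exactly one present node has an absent
    # (or no) parent, and every other present node's parent is present
    tops <- present_set[vapply(present_set, function(v) {
      p <- parent[[v]]
      is.na(p) || !pres[[p]]
    }, logical(1))]
    if (length(tops) != 1L) next
    losses <- sum(vapply(nodes, function(v) {
      p <- parent[[v]]
      !is.na(p) && pres[[p]] && !pres[[v]]
    }, logical(1)))
    if (losses < best) { best <- losses; best_gain <- tops }
  }
  list(n_losses = as.integer(best), gain_node = best_gain)
}

# Wagner oracle: enumerate all ancestral state vectors with states in
# 0..max(counts); return the global minimum cost.
wagner_brute <- function(counts, tree) {
  nodes <- tree$preorder
  internal <- nodes[!nodes %in% tree$leaves]
  parent <- tree$parent
  S <- max(counts)
  grid <- do.call(expand.grid, rep(list(0:S), length(internal)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- setNames(c(as.integer(grid[r, ]), unname(counts[tree$leaves])),
                   c(internal, tree$leaves))
    cost <- sum(vapply(nodes, function(v) {
      p <- parent[[v]]
      if (is.na(p)) 0L else abs(st[[p]] - st[[v]])
    }, integer(1)))
    if (cost < best) best <- cost
  }
  best
}

# MRCA by explicit parent-chain intersection (independent of package internals)
st_mrca_for_test <- function(tree, ids) {
  chains <- lapply(ids, function(id) {
    chain <- id
    while (!is.na(tree$parent[[chain[length(chain)]]]))
      chain <- c(chain, tree$parent[[chain[length(chain)]]])
    chain
  })
  common <- Reduce(intersect, chains)
  common[1L]
}

# exact upper-tail hypergeometric by direct binomial-coefficient arithmetic
hyper_tail_brute <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# textbook BH step-up, written as the explicit backward-minimum loop
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  adj[m] <- min(1, sorted[m])
  if (m > 1) for (i in (m - 1):1)
    adj[i] <- min(adj[i + 1], sorted[i] * m / i)
  out <- numeric(m)
  out[o] <- adj
  out
}
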