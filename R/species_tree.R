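#' Rooted species trees with stable node identifiers
#'
#' A `species_tree` wraps an [ape::phylo] topology and gives every node a
#' stable identifier: leaves are identified by their (unique) species labels,
#' internal nodes by their Newick label when one is present, otherwise by a
#' deterministic preorder identifier `"N1"`, `"N2"`, ... assigned from the
#' root down. These identifiers key every downstream event table, so repeated
#' runs on the same input name the same nodes.
#'
#' Trees are treated as rooted exactly as written; multifurcations are
#' permitted, unifurcations (internal nodes with a single child) are rejected.
#' Branch lengths, if present, are ignored: all reconstruction in this package
#' is topology-only.
#'
#' @param newick_text A single rooted Newick statement terminated by `";"`.
#' @return An object of class `species_tree` with components `phylo` (the
#'   underlying [ape::phylo]), `nodes` (a tibble with columns `id`, `parent`,
#'   `label`, `is_leaf`, `preorder`), and precomputed traversal indices.
#' @examples
#' tr <- parse_species_tree("((A,B),(C,D));")
#' tidy(tr)
#' @export
parse_species_tree <- function(newick_text) {
  check_newick_syntax(newick_text)
  phy <- tryCatch(
    ape::read.tree(text = newick_text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort("Newick parse error: no tree could be read.")
  if (inherits(phy, "multiPhylo"))
    abort("Expected a single Newick statement, found several.")
  new_species_tree(phy)
}

# cheap syntax pre-check so malformed input reports a character offset
check_newick_syntax <- function(text) {
  if (!is.character(text) || length(text) != 1)
    abort("`newick_text` must be a single character string.")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        abort(sprintf("Newick parse error: unbalanced ')' at character %d.", i))
    }
  }
  if (depth != 0L)
    abort(sprintf(
      "Newick parse error: %d unclosed '(' at end of input (character %d).",
      depth, length(chars)))
  if (!grepl(";", text, fixed = TRUE))
    abort(sprintf(
      "Newick parse error: missing terminating ';' (character %d).",
      length(chars) + 1L))
  invisible(TRUE)
}

# Build the species_tree structure from an ape phylo, assigning node ids.
new_species_tree <- function(phy) {
  ntip <- ape::Ntip(phy)
  if (ntip < 1L) abort("Tree has no leaves.")
  nnode <- phy$Nnode
  tips <- phy$tip.label
  if (anyNA(tips) || any(!nzchar(tips)))
    abort("Validation error: empty leaf label.")
  if (anyDuplicated(tips))
    abort(paste0("Validation error: duplicate leaf labels: ",
                 paste(unique(tips[duplicated(tips)]), collapse = ", "), "."))

  n_all <- ntip + nnode
  kids <- vector("list", n_all)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[r, 2])
  }
  n_children <- lengths(kids)
  if (any(n_children[(ntip + 1L):n_all] == 1L))
    abort("Validation error: unifurcation (internal node with a single child).")

  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  if (length(root) != 1L) abort("Validation error: tree must have exactly one root.")

  # preorder over ape indices, children in input (cladewise) order
  pre <- integer(n_all)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    k <- k + 1L
    pre[k] <- v
    if (n_children[v] > 0L) stack <- c(kids[[v]], stack)
  }

  labels <- phy$node.label %||% rep("", nnode)
  labels[is.na(labels)] <- ""
  ids <- character(n_all)
  ids[seq_len(ntip)] <- tips
  internal_rank <- 0L
  for (v in pre) {
    if (v > ntip) {
      internal_rank <- internal_rank + 1L
      lab <- labels[v - ntip]
      ids[v] <- if (nzchar(lab)) lab else sprintf("N%d", internal_rank)
    }
  }
  if (anyDuplicated(ids))
    abort(paste0("Validation error: node identifiers are not unique: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "), "."))

  parent_idx <- rep(NA_integer_, n_all)
  parent_idx[phy$edge[, 2]] <- phy$edge[, 1]

  nodes <- tibble(
    id = ids[pre],
    parent = ifelse(is.na(parent_idx[pre]), NA_character_, ids[parent_idx[pre]]),
    label = c(character(0), ifelse(pre > ntip, labels[pmax(pre - ntip, 1L)], NA_character_)),
    is_leaf = pre <= ntip,
    preorder = seq_len(n_all)
  )
  nodes$label[nodes$is_leaf] <- NA_character_
  nodes$label[!nodes$is_leaf & !nzchar(nodes$label %||% "")] <- NA_character_

  children <- setNames(lapply(seq_len(n_all), function(v) ids[kids[[v]]]), ids)
  preorder_ids <- ids[pre]
  postorder_ids <- rev(preorder_ids)

  # inclusive ancestor chains (self first, root last) and leaves below each node
  parent_map <- setNames(nodes$parent, nodes$id)
  ancestors <- lapply(ids, function(id) {
    chain <- id
    while (!is.na(parent_map[[chain[length(chain)]]]))
      chain <- c(chain, parent_map[[chain[length(chain)]]])
    chain
  })
  names(ancestors) <- ids

  leaves_below <- setNames(vector("list", n_all), ids)
  for (id in postorder_ids) {
    ch <- children[[id]]
    leaves_below[[id]] <- if (length(ch) == 0L) id else
      unlist(leaves_below[ch], use.names = FALSE)
  }

  # phylo copy carrying resolved ids as node labels, for serialization
  phy_out <- phy
  phy_out$node.label <- ids[(ntip + 1L):n_all]
  phy_out$edge.length <- NULL

  structure(
    list(phylo = phy_out, nodes = nodes, children = children,
         parent = parent_map, preorder = preorder_ids,
         postorder = postorder_ids, ancestors = ancestors,
         leaves_below = leaves_below, root = ids[root],
         leaves = tips),
    class = "species_tree")
}

#' Serialize a species tree back to Newick
#'
#' Internal nodes are written with their resolved identifiers, so a
#' parse/serialize/parse round trip yields an identical topology and
#' identifier set.
#'
#' @param tree A `species_tree`.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_species_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "species_tree"))
  txt <- ape::write.tree(tree$phylo)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d leaves, %d internal nodes, root %s\n",
              length(x$leaves), sum(!x$nodes$is_leaf), x$root))
  cat("  leaves:", paste(head(x$leaves, 8), collapse = ", "),
      if (length(x$leaves) > 8) "..." else "", "\n")
  invisible(x)
}

#' @describeIn parse_species_tree Tidy the node table of a species tree.
#' @param x A `species_tree`.
#' @param ... Unused.
#' @export
tidy.species_tree <- function(x, ...) x$nodes

# --- traversal helpers (internal) -------------------------------------------

st_is_leaf <- function(tree, id) id %in% tree$leaves

# most recent common ancestor of a set of node ids
st_mrca <- function(tree, ids) {
  ids <- unique(ids)
  if (length(ids) == 0L) return(NA_character_)
  if (length(ids) == 1L) return(ids)
  chain <- tree$ancestors[[ids[1L]]]
  for (id in ids[-1L]) chain <- chain[chain %in% tree$ancestors[[id]]]
  chain[1L] # ancestors are ordered self -> root; first common is deepest
}

# is `anc` an ancestor of (or equal to) `id`?
st_is_ancestor <- function(tree, anc, id) anc %in% tree$ancestors[[id]]
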