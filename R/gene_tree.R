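#' Rooted gene trees with species-tagged leaves
#'
#' A `gene_tree` is a rooted tree whose leaves carry both a species label and
#' a gene identifier, encoded in the Newick leaf label as
#' `species<sep>gene_id` (default separator `"|"`, split on the first
#' occurrence). Internal-node Newick labels, when present, are read as clade
#' support values and must be decimals in `[0, 1]`.
#'
#' @param newick_text A single rooted Newick statement.
#' @param orthogroup_id Label of the orthogroup this gene tree represents.
#' @param sep Separator between species and gene id in leaf labels.
#' @return An object of class `gene_tree`: components `phylo`, `nodes` (tibble
#'   with `id`, `parent`, `is_leaf`, `species`, `gene`, `support`),
#'   traversal indices, and `orthogroup_id`.
#' @examples
#' gt <- parse_gene_tree("((A|g1,B|g2)0.9,(A|g3,B|g4)1.0);", "OG1")
#' tidy(gt)
#' @export
parse_gene_tree <- function(newick_text, orthogroup_id = "OG", sep = "|") {
  check_newick_syntax(newick_text)
  phy <- tryCatch(
    ape::read.tree(text = newick_text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort("Newick parse error: no tree could be read.")

  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  n_all <- ntip + nnode

  # leaf labels must be unique for id purposes; gene trees usually guarantee it
  if (anyDuplicated(phy$tip.label))
    abort("Validation error: duplicate gene-tree leaf labels.")

  split_at <- regexpr(sep, phy$tip.label, fixed = TRUE)
  if (any(split_at < 0L))
    abort(sprintf(
      "Validation error: leaf label(s) without '%s' separator: %s",
      sep, paste(phy$tip.label[split_at < 0L], collapse = ", ")))
  species <- substr(phy$tip.label, 1L, split_at - 1L)
  gene <- substr(phy$tip.label, split_at + nchar(sep), nchar(phy$tip.label))
  if (any(!nzchar(species)) || any(!nzchar(gene)))
    abort("Validation error: empty species or gene id in leaf label.")

  raw_support <- phy$node.label %||% rep("", nnode)
  raw_support[is.na(raw_support)] <- ""
  support <- rep(NA_real_, nnode)
  has <- nzchar(raw_support)
  support[has] <- suppressWarnings(as.numeric(raw_support[has]))
  if (any(has & is.na(support)))
    abort("Validation error: non-numeric internal-node support label.")
  if (any(support < 0 | support > 1, na.rm = TRUE))
    abort("Validation error: support values must lie in [0, 1].")

  kids <- vector("list", n_all)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[r, 2])
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])

  pre <- integer(n_all); stack <- root; k <- 0L
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    k <- k + 1L; pre[k] <- v
    if (length(kids[[v]])) stack <- c(kids[[v]], stack)
  }

  ids <- character(n_all)
  ids[seq_len(ntip)] <- phy$tip.label
  rank <- 0L
  for (v in pre) if (v > ntip) { rank <- rank + 1L; ids[v] <- sprintf("G%d", rank) }

  parent_idx <- rep(NA_integer_, n_all)
  parent_idx[phy$edge[, 2]] <- phy$edge[, 1]

  nodes <- tibble(
    id = ids[pre],
    parent = ifelse(is.na(parent_idx[pre]), NA_character_, ids[parent_idx[pre]]),
    is_leaf = pre <= ntip,
    species = ifelse(pre <= ntip, species[pmax(pre, 1L)], NA_character_),
    gene = ifelse(pre <= ntip, gene[pmax(pre, 1L)], NA_character_),
    support = ifelse(pre > ntip, support[pmax(pre - ntip, 1L)], NA_real_)
  )

  structure(
    list(phylo = phy, nodes = nodes,
         children = setNames(lapply(seq_len(n_all), function(v) ids[kids[[v]]]), ids),
         parent = setNames(nodes$parent, nodes$id),
         preorder = ids[pre], postorder = rev(ids[pre]),
         root = ids[root], orthogroup_id = orthogroup_id, sep = sep),
    class = "gene_tree")
}

#' Read gene trees from files
#'
#' `read_gene_tree()` reads one Newick file; `read_gene_trees()` reads every
#' `.nwk`/`.tre`/`.txt` file in a directory, taking the orthogroup id from
#' the file name (without extension).
#'
#' @param path File (or directory) path.
#' @param orthogroup_id Orthogroup label; defaults to the file base name.
#' @inheritParams parse_gene_tree
#' @return A `gene_tree`, or for `read_gene_trees()` a named list of them.
#' @export
read_gene_tree <- function(path, orthogroup_id = NULL, sep = "|") {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  og <- orthogroup_id %||% sub("\\.[^.]*$", "", basename(path))
  parse_gene_tree(txt, orthogroup_id = og, sep = sep)
}

#' @rdname read_gene_tree
#' @export
read_gene_trees <- function(path, sep = "|") {
  files <- list.files(path, pattern = "\\.(nwk|tre|txt|newick)$",
                      full.names = TRUE)
  files <- sort(files)
  trees <- lapply(files, read_gene_tree, sep = sep)
  setNames(trees, vapply(trees, function(t) t$orthogroup_id, character(1)))
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %s: %d genes from %d species\n",
              x$orthogroup_id, sum(x$nodes$is_leaf),
              length(unique(x$nodes$species[x$nodes$is_leaf]))))
  invisible(x)
}

#' @describeIn parse_gene_tree Tidy the node table of a gene tree.
#' @param x A `gene_tree`.
#' @param ... Unused.
#' @export
tidy.gene_tree <- function(x, ...) x$nodes
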