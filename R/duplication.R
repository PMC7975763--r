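#' Classify gene-tree nodes as duplications or speciations
#'
#' Applies the species-overlap rule: an internal gene-tree node is a
#' duplication if at least two of its child subtrees share at least one
#' species (the same species appears on both sides, which a pure speciation
#' cannot produce). Clade support for the call is the overlap fraction
#' `|intersection| / |union|` of the species sets of the two
#' most-overlapping child subtrees; nodes with more than two children use
#' the child pair with the largest overlap fraction. Each node is mapped to
#' the species-tree MRCA of the species found beneath it.
#'
#' Gene trees must be rooted. A multifurcating root is the usual signature
#' of an unrooted tree and is rejected unless `assume_rooted = TRUE`; as a
#' convenience, `midpoint_root = TRUE` midpoint-roots a tree that carries
#' branch lengths (with a warning, since rooting choices move duplication
#' nodes).
#'
#' @param gtree A `gene_tree`.
#' @param stree The companion `species_tree` (every gene-tree leaf species
#'   must be one of its leaves).
#' @param assume_rooted Accept a multifurcating root as genuinely rooted.
#' @param midpoint_root Midpoint-root the gene tree first (requires branch
#'   lengths and the phangorn package).
#' @return A tibble with one row per internal gene-tree node: `orthogroup`,
#'   `node`, `event` (`"duplication"`/`"speciation"`), `support` (overlap
#'   fraction), `species_node` (mapped species-tree node), `n_species`.
#' @examples
#' st <- parse_species_tree("((A,B),(C,D));")
#' gt <- parse_gene_tree("((A|g1,B|g2),(A|g3,B|g4));", "OG1")
#' classify_gene_tree_nodes(gt, st)
#' @export
classify_gene_tree_nodes <- function(gtree, stree, assume_rooted = FALSE,
                                     midpoint_root = FALSE) {
  stopifnot(inherits(gtree, "gene_tree"), inherits(stree, "species_tree"))
  if (midpoint_root) {
    if (is.null(gtree$phylo$edge.length))
      abort("midpoint_root requires branch lengths on the gene tree.")
    if (!requireNamespace("phangorn", quietly = TRUE))
      abort("midpoint_root requires the phangorn package.")
    warn("Midpoint-rooting the gene tree; duplication placement depends on the root.")
    phy <- phangorn::midpoint(gtree$phylo)
    gtree <- parse_gene_tree(ape::write.tree(phy), gtree$orthogroup_id,
                             sep = gtree$sep)
  }
  root_children <- gtree$children[[gtree$root]]
  if (length(root_children) > 2L && !assume_rooted)
    abort(paste0(
      "Gene tree root is multifurcating, which usually means the tree is ",
      "unrooted. Root it first, or pass assume_rooted = TRUE if the ",
      "multifurcation is genuine."))

  leaf_sp <- gtree$nodes$species[gtree$nodes$is_leaf]
  unknown <- setdiff(unique(leaf_sp), stree$leaves)
  if (length(unknown))
    abort(paste0("Validation error: gene-tree species not in species tree: ",
                 paste(unknown, collapse = ", ")))

  # species set below each gene-tree node, postorder
  spset <- setNames(vector("list", length(gtree$preorder)), gtree$preorder)
  for (id in gtree$postorder) {
    ch <- gtree$children[[id]]
    spset[[id]] <- if (length(ch) == 0L)
      gtree$nodes$species[match(id, gtree$nodes$id)]
    else unique(unlist(spset[ch], use.names = FALSE))
  }

  internal <- gtree$preorder[!gtree$preorder %in%
                               gtree$nodes$id[gtree$nodes$is_leaf]]
  rows <- lapply(internal, function(id) {
    ch <- gtree$children[[id]]
    best <- 0
    any_overlap <- FALSE
    if (length(ch) >= 2L) {
      for (a in seq_len(length(ch) - 1L)) for (b in (a + 1L):length(ch)) {
        sa <- spset[[ch[a]]]; sb <- spset[[ch[b]]]
        inter <- length(intersect(sa, sb))
        if (inter > 0L) any_overlap <- TRUE
        frac <- inter / length(union(sa, sb))
        if (frac > best) best <- frac
      }
    }
    tibble(
      orthogroup = gtree$orthogroup_id,
      node = id,
      event = if (any_overlap) "duplication" else "speciation",
      support = best,
      species_node = st_mrca(stree, spset[[id]]),
      n_species = length(spset[[id]])
    )
  })
  bind_rows(rows)
}

#' Tally duplication events per species-tree node
#'
#' Discards duplication calls whose clade support falls below
#' `min_support` (default 0.50, retained inclusively) and reports, for each
#' species-tree node, the total number of retained duplication events and
#' the number of distinct orthogroups that duplicated there one or more
#' times.
#'
#' @param events Classified node table(s) from [classify_gene_tree_nodes()]
#'   (rows from several gene trees may be bound together).
#' @param min_support Minimum clade support for a retained event.
#' @param tree Optional `species_tree`; when given, nodes with zero events
#'   are included so the table covers the whole tree.
#' @return A tibble with columns `species_node`, `n_events`,
#'   `n_orthogroups`.
#' @export
tally_duplications <- function(events, min_support = 0.5, tree = NULL) {
  assert_prob(min_support, "min_support")
  kept <- filter(events, .data$event == "duplication",
                 .data$support >= min_support)
  out <- kept %>%
    group_by(.data$species_node) %>%
    summarise(n_events = n(),
              n_orthogroups = n_distinct(.data$orthogroup),
              .groups = "drop")
  if (!is.null(tree)) {
    base <- tibble(species_node = tree$preorder)
    out <- left_join(base, out, by = "species_node") %>%
      mutate(n_events = tidyr::replace_na(.data$n_events, 0L),
             n_orthogroups = tidyr::replace_na(.data$n_orthogroups, 0L))
  }
  out
}

#' Write a duplication-event table
#'
#' Mirrors the consumed duplications-table dialect: one row per retained
#' duplication with orthogroup, gene-tree node, mapped species-tree node and
#' clade support.
#'
#' @param events Classified node table from [classify_gene_tree_nodes()].
#' @param path Output path.
#' @param min_support Support cutoff recorded in the header and applied.
#' @return `path`, invisibly.
#' @export
write_duplications <- function(events, path, min_support = 0.5) {
  kept <- filter(events, .data$event == "duplication",
                 .data$support >= min_support) %>%
    select("orthogroup", "node", "species_node", "support")
  write_tsv_provenance(kept, path, params = list(min_support = min_support))
}
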