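#' Dollo parsimony reconstruction of a single presence/absence profile
#'
#' Under Dollo parsimony an orthogroup may be gained exactly once but lost
#' any number of times. The unique most-parsimonious solution places the
#' gain at the most recent common ancestor (MRCA) of the leaves where the
#' orthogroup is present; within that gain subtree a node is reconstructed
#' present if and only if at least one descendant leaf is present, and each
#' edge from a present parent to an absent child is a loss. This placement
#' pushes the gain back in time as far as the data demand and achieves the
#' minimum possible number of losses given a single gain.
#'
#' @param presence Named logical vector, one entry per species-tree leaf.
#' @param tree A `species_tree`.
#' @return A list with components `gain_node` (node id, or `NA` when the
#'   orthogroup is absent from every leaf), `loss_edges` (ids of child nodes
#'   whose incoming edge carries a loss), `n_losses`, and `presence` (named
#'   logical over all node ids).
#' @examples
#' tr <- parse_species_tree("((A,B),(C,D));")
#' dollo_reconstruct(c(A = TRUE, B = FALSE, C = TRUE, D = FALSE), tr)
#' @export
dollo_reconstruct <- function(presence, tree) {
  stopifnot(inherits(tree, "species_tree"))
  missing_lv <- setdiff(tree$leaves, names(presence))
  if (length(missing_lv))
    abort(paste0("Validation error: profile missing leaves: ",
                 paste(missing_lv, collapse = ", ")))
  presence <- as.logical(presence[tree$leaves])

  ids <- tree$preorder
  pres <- setNames(rep(FALSE, length(ids)), ids)
  present_leaves <- tree$leaves[presence]
  if (length(present_leaves) == 0L)
    return(list(gain_node = NA_character_, loss_edges = character(0),
                n_losses = 0L, presence = pres))

  gain <- st_mrca(tree, present_leaves)
  # observed: >=1 present descendant leaf (postorder accumulation)
  obs <- setNames(rep(FALSE, length(ids)), ids)
  obs[present_leaves] <- TRUE
  for (id in tree$postorder) {
    ch <- tree$children[[id]]
    if (length(ch)) obs[id] <- any(obs[ch])
  }
  in_gain <- vapply(ids, function(id) st_is_ancestor(tree, gain, id), logical(1))
  pres[ids] <- in_gain & obs[ids]

  parent <- tree$parent
  losses <- ids[!is.na(parent[ids]) & !pres[ids] &
                  pres[ifelse(is.na(parent[ids]), ids, parent[ids])]]
  list(gain_node = gain, loss_edges = losses, n_losses = length(losses),
       presence = pres)
}

# min-plus distance transform: m[s] = min_t cost[t] + |s - t|, O(S)
linear_cost_transform <- function(cost) {
  n <- length(cost)
  m <- cost
  if (n > 1L) {
    for (i in 2:n) m[i] <- min(m[i], m[i - 1L] + 1)
    for (i in (n - 1L):1L) m[i] <- min(m[i], m[i + 1L] + 1)
  }
  m
}

#' Unweighted Wagner parsimony on integer copy number
#'
#' Sankoff dynamic programming over states `0..max_state` with symmetric
#' unit cost per copy gained or lost on an edge (`|parent - child|`),
#' multifurcation-safe. Bottom-up, each node's cost vector is accumulated
#' with an O(states) linear-cost (distance-transform) pass per child.
#' Top-down, each node takes the state minimizing its subtree cost plus the
#' step from the assigned parent state, breaking ties toward the state
#' closest to the parent and then toward the smaller state; the root takes
#' the smallest state in its minimal-cost set. This deterministic rule is
#' biased against inventing ancestral copies.
#'
#' Leaf counts larger than `max_state` are capped with a warning before the
#' dynamic program runs.
#'
#' @param counts Named non-negative integer vector, one entry per leaf.
#' @param tree A `species_tree`.
#' @param max_state Upper bound on ancestral copy number (default 64).
#' @return A list with `state` (named integer over all node ids) and `cost`
#'   (the minimal total parsimony cost).
#' @examples
#' tr <- parse_species_tree("((A,B),(C,D));")
#' wagner_reconstruct(c(A = 2, B = 0, C = 2, D = 2), tr)
#' @export
wagner_reconstruct <- function(counts, tree, max_state = 64L) {
  stopifnot(inherits(tree, "species_tree"))
  missing_lv <- setdiff(tree$leaves, names(counts))
  if (length(missing_lv))
    abort(paste0("Validation error: counts missing leaves: ",
                 paste(missing_lv, collapse = ", ")))
  counts <- counts[tree$leaves]
  if (any(is.na(counts) | counts < 0 | counts != floor(counts)))
    abort("Validation error: leaf counts must be non-negative integers.")
  if (any(counts > max_state)) {
    warn(sprintf("Capping %d leaf count(s) at max_state = %d.",
                 sum(counts > max_state), max_state))
    counts <- pmin(counts, max_state)
  }
  S <- min(max_state, max(counts)) # optimal states never exceed the leaf maximum
  n_states <- S + 1L

  ids <- tree$preorder
  cost <- matrix(Inf, nrow = length(ids), ncol = n_states,
                 dimnames = list(ids, NULL))
  for (id in tree$postorder) {
    ch <- tree$children[[id]]
    if (length(ch) == 0L) {
      cost[id, ] <- Inf
      cost[id, counts[[id]] + 1L] <- 0
    } else {
      acc <- numeric(n_states)
      for (c_id in ch) acc <- acc + linear_cost_transform(cost[c_id, ])
      cost[id, ] <- acc
    }
  }

  state <- setNames(integer(length(ids)), ids)
  root_costs <- cost[tree$root, ]
  state[tree$root] <- which(root_costs == min(root_costs))[1L] - 1L
  for (id in ids) {
    if (id == tree$root) next
    p_state <- state[[tree$parent[[id]]]]
    g <- cost[id, ] + abs(seq_len(n_states) - 1L - p_state)
    cand <- which(g == min(g)) - 1L
    cand <- cand[order(abs(cand - p_state), cand)]
    state[id] <- cand[1L]
  }
  list(state = state, cost = min(root_costs))
}

#' Reconstruct ancestral orthogroup content under Dollo and Wagner parsimony
#'
#' Runs [dollo_reconstruct()] (presence/absence; a leaf count of zero is
#' absence) and [wagner_reconstruct()] (copy number) for every orthogroup of
#' a count matrix over the same species tree, and derives the per-node event
#' tallies. The two parsimony criteria bracket the plausible history: Dollo
#' is the conservative estimator of gains near the leaves (a single gain is
#' pushed back to the MRCA of the present species), Wagner of gains near the
#' root (independent gains are allowed when they cost less than repeated
#' losses).
#'
#' @param counts A count-matrix tibble (first column `orthogroup`, then one
#'   integer column per species; see [read_count_matrix()]).
#' @param tree A `species_tree` whose leaves match the matrix species.
#' @param max_state Copy-number cap for the Wagner dynamic program.
#' @return A `gene_content_recon` object with components
#'   \describe{
#'     \item{states}{tibble: `orthogroup`, `node`, `dollo_present`,
#'       `wagner_state`}
#'     \item{events}{tibble of per-orthogroup events: `orthogroup`, `node`,
#'       `method` (`"dollo"`/`"wagner"`), `event`
#'       (`"gain"`/`"loss"`/`"expansion"`/`"contraction"`)}
#'     \item{node_events}{per-node tallies from [tally_events()]}
#'     \item{summary}{per-node summary from [summarize_tree()]}
#'     \item{dollo}{tibble: `orthogroup`, `gain_node`, `n_losses`}
#'     \item{wagner}{tibble: `orthogroup`, `cost`}
#'   }
#'   [tidy()] returns `states`, [glance()] run-level totals, [autoplot()]
#'   the per-node gain/loss bar chart.
#' @export
reconstruct_gene_content <- function(counts, tree, max_state = 64L) {
  stopifnot(inherits(tree, "species_tree"))
  al <- align_inputs(counts, tree, strict = TRUE)
  counts <- al$counts; tree <- al$tree

  ogs <- counts$orthogroup
  mat <- as.matrix(counts[, tree$leaves, drop = FALSE])
  rownames(mat) <- ogs
  ids <- tree$preorder
  n_og <- length(ogs)

  dollo_p <- matrix(FALSE, n_og, length(ids), dimnames = list(ogs, ids))
  wagner_s <- matrix(0L, n_og, length(ids), dimnames = list(ogs, ids))
  gain_nodes <- character(n_og)
  n_losses <- integer(n_og)
  costs <- integer(n_og)

  for (i in seq_len(n_og)) {
    cnt <- mat[i, ]
    d <- dollo_reconstruct(cnt > 0, tree)
    w <- wagner_reconstruct(cnt, tree, max_state = max_state)
    dollo_p[i, ] <- d$presence[ids]
    wagner_s[i, ] <- w$state[ids]
    gain_nodes[i] <- d$gain_node
    n_losses[i] <- d$n_losses
    costs[i] <- w$cost
  }

  states <- tibble(
    orthogroup = rep(ogs, each = length(ids)),
    node = rep(ids, times = n_og),
    dollo_present = as.vector(t(dollo_p)),
    wagner_state = as.vector(t(wagner_s))
  )
  events <- orthogroup_events(states, tree)
  node_events <- tally_events(states, tree, events = events)
  summary <- summarize_tree(node_events, states, tree)

  structure(
    list(states = states, events = events, node_events = node_events,
         summary = summary,
         dollo = tibble(orthogroup = ogs, gain_node = gain_nodes,
                        n_losses = n_losses),
         wagner = tibble(orthogroup = ogs, cost = costs),
         tree = tree, max_state = max_state),
    class = "gene_content_recon")
}

#' Per-orthogroup event lists from reconstructed states
#'
#' Derives, for every orthogroup and node, the parent-to-child transition
#' events: a gain is a shift from absence at the parent to presence at the
#' node, a loss the opposite; an expansion is a shift from the single-copy
#' state at the parent to multi-copy at the node, a contraction the
#' opposite. Gain and expansion are mutually exclusive at a node (a 0 to
#' multi-copy shift counts as a gain only). At the root, which has no
#' parent, a gain is charged when the root is reconstructed present
#' (otherwise the orthogroup would exist nowhere), but no expansion or
#' contraction is charged since those are defined strictly as
#' parent-to-child shifts.
#'
#' @param states The `states` tibble of a reconstruction (columns
#'   `orthogroup`, `node`, `dollo_present`, `wagner_state`).
#' @param tree The `species_tree` used for reconstruction.
#' @return A tibble with columns `orthogroup`, `node`, `method`, `event`.
#' @export
orthogroup_events <- function(states, tree) {
  stopifnot(all(c("orthogroup", "node", "dollo_present", "wagner_state") %in%
                  names(states)))
  parent <- tree$parent
  st <- states %>%
    mutate(parent_node = unname(parent[.data$node]))
  pst <- states %>%
    select(orthogroup, parent_node = "node",
           p_dollo = "dollo_present", p_wagner = "wagner_state")
  st <- left_join(st, pst, by = c("orthogroup", "parent_node"))

  is_root <- is.na(st$parent_node)
  d_gain <- ifelse(is_root, st$dollo_present, !st$p_dollo & st$dollo_present)
  d_loss <- ifelse(is_root, FALSE, st$p_dollo & !st$dollo_present)
  w_gain <- ifelse(is_root, st$wagner_state > 0,
                   st$p_wagner == 0 & st$wagner_state > 0)
  w_loss <- ifelse(is_root, FALSE, st$p_wagner > 0 & st$wagner_state == 0)
  w_exp <- ifelse(is_root, FALSE, st$p_wagner == 1 & st$wagner_state >= 2)
  w_con <- ifelse(is_root, FALSE, st$p_wagner >= 2 & st$wagner_state == 1)

  bind_rows(
    tibble(orthogroup = st$orthogroup[d_gain], node = st$node[d_gain],
           method = "dollo", event = "gain"),
    tibble(orthogroup = st$orthogroup[d_loss], node = st$node[d_loss],
           method = "dollo", event = "loss"),
    tibble(orthogroup = st$orthogroup[w_gain], node = st$node[w_gain],
           method = "wagner", event = "gain"),
    tibble(orthogroup = st$orthogroup[w_loss], node = st$node[w_loss],
           method = "wagner", event = "loss"),
    tibble(orthogroup = st$orthogroup[w_exp], node = st$node[w_exp],
           method = "wagner", event = "expansion"),
    tibble(orthogroup = st$orthogroup[w_con], node = st$node[w_con],
           method = "wagner", event = "contraction")
  ) %>% arrange(.data$orthogroup, .data$node, .data$method, .data$event)
}

#' Tally gains, losses, expansions and contractions per node
#'
#' Sums the per-orthogroup indicator events of [orthogroup_events()] over
#' orthogroups, reporting Dollo-based and Wagner-based gain/loss tallies
#' side by side together with Wagner expansions/contractions and the net
#' columns shown in ancestral-content bar charts (`net_gain = gains -
#' losses` per method, `net_expansion = expansions - contractions`).
#'
#' @inheritParams orthogroup_events
#' @param events Optional precomputed event tibble (recomputed otherwise).
#' @return A tibble with one row per tree node.
#' @export
tally_events <- function(states, tree, events = NULL) {
  events <- events %||% orthogroup_events(states, tree)
  base <- tibble(node = tree$preorder)
  wide <- events %>%
    count(.data$node, .data$method, .data$event) %>%
    mutate(col = paste(.data$method, .data$event, sep = "_")) %>%
    select("node", "col", "n") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "n", values_fill = 0L)
  need <- c("dollo_gain", "dollo_loss", "wagner_gain", "wagner_loss",
            "wagner_expansion", "wagner_contraction")
  for (cn in setdiff(need, names(wide))) wide[[cn]] <- 0L
  out <- left_join(base, wide, by = "node")
  out[need][is.na(out[need])] <- 0L
  out %>%
    rename(dollo_gains = "dollo_gain", dollo_losses = "dollo_loss",
           wagner_gains = "wagner_gain", wagner_losses = "wagner_loss",
           expansions = "wagner_expansion", contractions = "wagner_contraction") %>%
    mutate(
      dollo_net_gain = .data$dollo_gains - .data$dollo_losses,
      wagner_net_gain = .data$wagner_gains - .data$wagner_losses,
      net_expansion = .data$expansions - .data$contractions
    )
}

#' Per-node summary with ancestral totals and consistency checksum
#'
#' Adds, for each node and method, the ancestral orthogroup total (number of
#' orthogroups reconstructed present) and verifies the bookkeeping identity
#' `total(v) = total(parent(v)) + gains(v) - losses(v)` (for the root,
#' `total(root) = gains(root)`). A checksum failure indicates an internal
#' inconsistency and raises an error; it cannot occur on valid
#' reconstructions.
#'
#' Because most species in comparative transcriptome studies contribute
#' expression evidence only, absence at a leaf may reflect non-expression
#' rather than gene loss; the optional `data_type` annotation is carried
#' through so reports can surface this caveat per species.
#'
#' @param node_events Per-node tallies from [tally_events()].
#' @param states The `states` tibble of the reconstruction.
#' @param tree The `species_tree`.
#' @param data_type Optional named character vector (by species) recording
#'   each leaf's data type, e.g. `"genome"` or `"transcriptome"`.
#' @return A tibble with one row per node: tallies, `dollo_total`,
#'   `wagner_total`, `is_leaf`, `data_type`.
#' @export
summarize_tree <- function(node_events, states, tree, data_type = NULL) {
  totals <- states %>%
    group_by(.data$node) %>%
    summarise(dollo_total = sum(.data$dollo_present),
              wagner_total = sum(.data$wagner_state > 0), .groups = "drop")
  out <- left_join(node_events, totals, by = "node") %>%
    mutate(dollo_total = as.integer(tidyr::replace_na(.data$dollo_total, 0L)),
           wagner_total = as.integer(tidyr::replace_na(.data$wagner_total, 0L)),
           is_leaf = .data$node %in% tree$leaves)

  parent <- tree$parent
  for (i in seq_len(nrow(out))) {
    v <- out$node[i]
    p <- parent[[v]]
    d_expect <- if (is.na(p)) out$dollo_gains[i] else
      out$dollo_total[match(p, out$node)] + out$dollo_gains[i] - out$dollo_losses[i]
    w_expect <- if (is.na(p)) out$wagner_gains[i] else
      out$wagner_total[match(p, out$node)] + out$wagner_gains[i] - out$wagner_losses[i]
    if (d_expect != out$dollo_total[i] || w_expect != out$wagner_total[i])
      abort(sprintf(
        "Internal consistency error: checksum failed at node %s (this is a bug).", v))
  }
  out$data_type <- if (is.null(data_type)) NA_character_ else
    unname(data_type[out$node])
  out
}

#' @export
print.gene_content_recon <- function(x, ...) {
  cat(sprintf(
    "<gene_content_recon> %d orthogroups x %d nodes (%d leaves); Wagner max_state %d\n",
    length(unique(x$states$orthogroup)), length(x$tree$preorder),
    length(x$tree$leaves), x$max_state))
  cat("  per-node tallies in $node_events; states in $states\n")
  invisible(x)
}

#' @describeIn reconstruct_gene_content Per-orthogroup, per-node ancestral
#'   states as a tibble.
#' @param x,object A `gene_content_recon` object.
#' @param ... Unused.
#' @export
tidy.gene_content_recon <- function(x, ...) x$states

#' @describeIn reconstruct_gene_content One-row run summary (orthogroup and
#'   event totals).
#' @export
glance.gene_content_recon <- function(x, ...) {
  ne <- x$node_events
  tibble(
    n_orthogroups = length(unique(x$states$orthogroup)),
    n_nodes = length(x$tree$preorder),
    dollo_gains = sum(ne$dollo_gains), dollo_losses = sum(ne$dollo_losses),
    wagner_gains = sum(ne$wagner_gains), wagner_losses = sum(ne$wagner_losses),
    expansions = sum(ne$expansions), contractions = sum(ne$contractions),
    wagner_total_cost = sum(x$wagner$cost)
  )
}

#' @describeIn reconstruct_gene_content Diverging per-node bar chart of
#'   gains (up) and losses (down) under each method, with expansions and
#'   contractions alongside.
#' @export
autoplot.gene_content_recon <- function(object, ...) {
  ne <- object$node_events
  long <- bind_rows(
    tibble(node = ne$node, panel = "Dollo gain/loss",
           up = ne$dollo_gains, down = ne$dollo_losses),
    tibble(node = ne$node, panel = "Wagner gain/loss",
           up = ne$wagner_gains, down = ne$wagner_losses),
    tibble(node = ne$node, panel = "Wagner expansion/contraction",
           up = ne$expansions, down = ne$contractions)
  ) %>%
    tidyr::pivot_longer(c("up", "down"), names_to = "direction",
                        values_to = "n") %>%
    mutate(n = ifelse(.data$direction == "down", -.data$n, .data$n),
           node = factor(.data$node, levels = object$tree$preorder))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(up = "steelblue", down = "indianred"),
      labels = c(up = "gained/expanded", down = "lost/contracted")) +
    ggplot2::labs(x = "species-tree node", y = "orthogroups", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write reconstruction outputs
#'
#' Writes `ancestral_states.tsv` (orthogroup x node, both methods),
#' `node_events.tsv` (per-node tallies and totals) and
#' `per_orthogroup_events.tsv` (event lists) into a directory.
#'
#' @param recon A `gene_content_recon` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_reconstruction <- function(recon, dir) {
  stopifnot(inherits(recon, "gene_content_recon"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(max_state = recon$max_state)
  write_tsv_provenance(recon$states, file.path(dir, "ancestral_states.tsv"), p)
  write_tsv_provenance(recon$summary, file.path(dir, "node_events.tsv"), p)
  write_tsv_provenance(recon$events, file.path(dir, "per_orthogroup_events.tsv"), p)
  invisible(dir)
}
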