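#' Simulate gene-family histories on a species tree
#'
#' Generates orthogroup histories by branch-located gain, per-branch
#' whole-family loss, and per-copy duplication, recording the full event
#' log so downstream reconstructions can be checked against a known truth.
#'
#' For each orthogroup a gain branch is chosen: the root with probability
#' `root_gain_fraction`, otherwise uniformly among the non-root branches
#' (each branch is identified by its child-end node). The family starts
#' with one copy at the gain node. Along every descendant edge the whole
#' family is lost with probability `p_loss`; otherwise each copy
#' independently duplicates with probability `p_dup`, adding one extra copy
#' per success. Loss is whole-family per branch (not per copy) so that at
#' `p_dup = 0` the generative model coincides exactly with the model class
#' Dollo parsimony assumes — gained once, lost as a unit.
#'
#' All randomness flows from the single `seed`; repeated calls with the
#' same arguments are identical.
#'
#' @param tree A `species_tree`.
#' @param n_orthogroups Number of orthogroups to simulate.
#' @param p_loss Per-branch whole-family loss probability.
#' @param p_dup Per-copy per-branch duplication probability (at most one
#'   duplication per copy per branch).
#' @param root_gain_fraction Probability that an orthogroup is gained at
#'   the root rather than on a uniformly chosen non-root branch.
#' @param seed Integer seed.
#' @return A `gene_content_sim` object: list with
#'   \describe{
#'     \item{counts}{the emitted count-matrix tibble (leaf copy numbers)}
#'     \item{history}{the ground truth: `params`, `gains` (orthogroup,
#'       gain_node), `states` (orthogroup, node, count — true copy number
#'       at every node), `events` (orthogroup, node = child end of the
#'       edge, type `"loss"`/`"duplication"`, n)}
#'   }
#' @export
simulate_gene_content <- function(tree, n_orthogroups = 100L, p_loss = 0.05,
                                  p_dup = 0.05, root_gain_fraction = 0.5,
                                  seed = 1L) {
  stopifnot(inherits(tree, "species_tree"))
  if (n_orthogroups < 1L) abort("`n_orthogroups` must be >= 1.")
  assert_prob(p_loss, "p_loss")
  assert_prob(p_dup, "p_dup")
  assert_prob(root_gain_fraction, "root_gain_fraction")

  ids <- tree$preorder
  non_root <- setdiff(ids, tree$root)
  ogs <- sprintf("OG%04d", seq_len(n_orthogroups))

  states <- matrix(0L, n_orthogroups, length(ids), dimnames = list(ogs, ids))
  gains <- character(n_orthogroups)
  ev_og <- character(0); ev_node <- character(0)
  ev_type <- character(0); ev_n <- integer(0)

  with_seed(seed, {
    for (i in seq_len(n_orthogroups)) {
      gain <- if (runif(1) < root_gain_fraction || length(non_root) == 0L)
        tree$root else sample(non_root, 1L)
      gains[i] <- gain
      states[i, gain] <- 1L
      # preorder guarantees parents are settled before children
      for (v in ids) {
        if (v == gain || !st_is_ancestor(tree, gain, v) || v == tree$root) next
        u <- tree$parent[[v]]
        k <- states[i, u]
        if (k == 0L) next
        if (runif(1) < p_loss) {
          states[i, v] <- 0L
          ev_og <- c(ev_og, ogs[i]); ev_node <- c(ev_node, v)
          ev_type <- c(ev_type, "loss"); ev_n <- c(ev_n, 1L)
        } else {
          nd <- rbinom(1L, k, p_dup)
          states[i, v] <- k + nd
          if (nd > 0L) {
            ev_og <- c(ev_og, ogs[i]); ev_node <- c(ev_node, v)
            ev_type <- c(ev_type, "duplication"); ev_n <- c(ev_n, nd)
          }
        }
      }
    }
  })

  counts <- as_tibble(cbind(
    tibble(orthogroup = ogs),
    as.data.frame(states[, tree$leaves, drop = FALSE])
  ))
  history <- list(
    params = list(n_orthogroups = n_orthogroups, p_loss = p_loss,
                  p_dup = p_dup, root_gain_fraction = root_gain_fraction,
                  seed = seed),
    gains = tibble(orthogroup = ogs, gain_node = gains),
    states = tibble(orthogroup = rep(ogs, each = length(ids)),
                    node = rep(ids, times = n_orthogroups),
                    count = as.vector(t(states))),
    events = tibble(orthogroup = ev_og, node = ev_node, type = ev_type,
                    n = ev_n)
  )
  structure(list(counts = counts, history = history, tree = tree),
            class = "gene_content_sim")
}

#' @export
print.gene_content_sim <- function(x, ...) {
  p <- x$history$params
  cat(sprintf(
    "<gene_content_sim> %d orthogroups on %d leaves (p_loss %.3g, p_dup %.3g, seed %d)\n",
    p$n_orthogroups, length(x$tree$leaves), p$p_loss, p$p_dup, p$seed))
  invisible(x)
}

#' True per-node event tallies of a simulated history
#'
#' Derives from the recorded true states the same per-node quantities that
#' [tally_events()] reports for a reconstruction: gains (the gain node),
#' losses (recorded loss events), expansions (true parent count 1, child
#' count >= 2) and contractions (>= 2 to 1). Used for closed-loop recovery
#' tests.
#'
#' @param history The `history` element of a `gene_content_sim` (or the sim
#'   object itself).
#' @param tree The `species_tree` the history was simulated on.
#' @return A tibble with one row per node: `node`, `gains`, `losses`,
#'   `expansions`, `contractions`.
#' @export
history_event_tally <- function(history, tree) {
  if (inherits(history, "gene_content_sim")) history <- history$history
  st <- history$states %>%
    mutate(parent_node = unname(tree$parent[.data$node]))
  pst <- history$states %>%
    select("orthogroup", parent_node = "node", p_count = "count")
  st <- left_join(st, pst, by = c("orthogroup", "parent_node"))
  gains_tbl <- count(history$gains, node = .data$gain_node, name = "gains")
  tibble(node = tree$preorder) %>%
    left_join(gains_tbl, by = "node") %>%
    left_join(
      st %>% group_by(.data$node) %>%
        summarise(
          losses = sum(!is.na(.data$p_count) & .data$p_count > 0 & .data$count == 0),
          expansions = sum(!is.na(.data$p_count) & .data$p_count == 1 & .data$count >= 2),
          contractions = sum(!is.na(.data$p_count) & .data$p_count >= 2 & .data$count == 1),
          .groups = "drop"),
      by = "node") %>%
    mutate(gains = tidyr::replace_na(.data$gains, 0L))
}

#' True per-node duplication tallies of a simulated history
#'
#' @inheritParams history_event_tally
#' @return A tibble with columns `species_node`, `n_events`,
#'   `n_orthogroups`, matching the shape of [tally_duplications()].
#' @export
history_duplication_tally <- function(history, tree) {
  if (inherits(history, "gene_content_sim")) history <- history$history
  dup <- filter(history$events, .data$type == "duplication")
  out <- dup %>%
    group_by(species_node = .data$node) %>%
    summarise(n_events = sum(.data$n),
              n_orthogroups = n_distinct(.data$orthogroup), .groups = "drop")
  tibble(species_node = tree$preorder) %>%
    left_join(out, by = "species_node") %>%
    mutate(n_events = tidyr::replace_na(.data$n_events, 0L),
           n_orthogroups = tidyr::replace_na(.data$n_orthogroups, 0L))
}

#' Grow gene trees from a simulated history
#'
#' Replays the event log of a simulated history deterministically: the gene
#' tree of each orthogroup is grown by walking the species tree from the
#' gain branch; duplication events create bifurcations whose two daughter
#' lineages each inherit the remaining species-tree descent, and losses
#' prune whole subtrees. When an edge carries `d` duplication events among
#' `k` incoming copies, the first `d` copies (in lineage order) duplicate —
#' which copies duplicate does not affect leaf counts, so the replay is
#' consistent with the emitted count matrix by construction. Speciation
#' nodes with a single surviving child edge are suppressed (a lineage
#' passing through leaves no trace in the gene tree).
#'
#' Leaves are labeled `species|<orthogroup>_g<N>`; every internal node gets
#' support 1.0. An event row whose node equals the gain node is interpreted
#' as a duplication on the gain branch itself (above the first speciation).
#' Orthogroups with fewer than two surviving genes yield no tree.
#'
#' @param sim A `gene_content_sim` (or its `history` element).
#' @param tree The `species_tree` used for simulation (optional when `sim`
#'   is the full object).
#' @return A named list of `gene_tree` objects, one per orthogroup with at
#'   least two surviving genes.
#' @export
simulate_gene_trees <- function(sim, tree = NULL) {
  history <- if (inherits(sim, "gene_content_sim")) sim$history else sim
  tree <- tree %||% sim$tree
  stopifnot(inherits(tree, "species_tree"))

  loss_set <- with(history$events[history$events$type == "loss", ],
                   paste(orthogroup, node))
  dup_n <- history$events[history$events$type == "duplication", ]
  dup_key <- setNames(dup_n$n, paste(dup_n$orthogroup, dup_n$node))

  grow_one <- function(og, gain) {
    counter <- 0L
    # returns a character vector of newick substrings, one per copy entering
    # node v (NA when a copy leaves no surviving descendants)
    grow <- function(v, k_in) {
      if (k_in == 0L) return(character(0))
      if (st_is_leaf(tree, v)) {
        labs <- character(k_in)
        for (j in seq_len(k_in)) {
          counter <<- counter + 1L
          labs[j] <- sprintf("%s|%s_g%d", v, og, counter)
        }
        return(labs)
      }
      ch <- tree$children[[v]]
      kept <- ch[!(paste(og, ch) %in% loss_set)]
      per_child <- vector("list", length(kept))
      for (ci in seq_along(kept)) {
        c_id <- kept[ci]
        nd <- unname(dup_key[paste(og, c_id)])
        nd <- if (is.na(nd) || !length(nd)) 0L else min(nd, k_in)
        k_out <- k_in + nd
        subs <- grow(c_id, k_out)
        # map the k_out child slots back onto the k_in parent copies:
        # copy j contributes 2 adjacent slots if j <= nd, else 1
        res <- character(k_in)
        pos <- 1L
        for (j in seq_len(k_in)) {
          take <- if (j <= nd) 2L else 1L
          part <- subs[pos:(pos + take - 1L)]
          pos <- pos + take
          part <- part[!is.na(part)]
          res[j] <- if (length(part) == 0L) NA_character_
          else if (length(part) == 1L) part
          else paste0("(", paste(part, collapse = ","), ")1.0") # duplication node
        }
        per_child[[ci]] <- res
      }
      out <- character(k_in)
      for (j in seq_len(k_in)) {
        parts <- vapply(per_child, function(p) p[j], character(1))
        parts <- parts[!is.na(parts)]
        out[j] <- if (length(parts) == 0L) NA_character_
        else if (length(parts) == 1L) parts
        else paste0("(", paste(parts, collapse = ","), ")1.0") # speciation node
      }
      out
    }
    # duplications on the gain branch itself (event node == gain node)
    nd0 <- unname(dup_key[paste(og, gain)])
    nd0 <- if (is.na(nd0) || !length(nd0)) 0L else nd0
    top <- grow(gain, 1L + nd0)
    top <- top[!is.na(top)]
    if (length(top) == 0L) return(NULL)
    nwk <- if (length(top) == 1L) top else
      paste0("(", paste(top, collapse = ","), ")1.0")
    if (counter < 2L) return(NULL)
    # a bare-leaf newick needs wrapping to be a valid rooted statement
    if (!startsWith(nwk, "(")) nwk <- paste0("(", nwk, ");") else
      nwk <- paste0(nwk, ";")
    parse_gene_tree(nwk, orthogroup_id = og)
  }

  trees <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(history$gains))) {
    og <- history$gains$orthogroup[i]
    gt <- grow_one(og, history$gains$gain_node[i])
    if (is.null(gt)) skipped <- c(skipped, og) else trees[[og]] <- gt
  }
  if (length(skipped))
    inform(paste0(length(skipped),
                  " orthogroup(s) with < 2 surviving genes: no tree emitted."))
  trees
}

#' Simulate a homology-hit table with known contaminants
#'
#' Builds a hit table exercising the Alien Index screen. Clean queries get
#' their best hit from the in-group (normalized in-group score 1.0) and all
#' out-group scores strictly below `1 - 0.05` of it, so their Alien Index
#' falls below the 0.05 flagging threshold by construction. Contaminant
#' queries get their best hit from the out-group, with the best in-group
#' hit at most 95% of it, so their Alien Index is at least 0.05. Truth
#' labels are recorded.
#'
#' @param n_queries Number of queries.
#' @param contamination_fraction Fraction of queries constructed as
#'   contaminants.
#' @param seed Integer seed.
#' @param n_extra_hits Additional (non-best) hits per query and group.
#' @return A list with `hits` (query, subject, bitscore), `lineage_map`
#'   (prefix to group), and `truth` (query, contaminant flag).
#' @export
simulate_hit_table <- function(n_queries = 200L, contamination_fraction = 0.1,
                               seed = 1L, n_extra_hits = 2L) {
  assert_prob(contamination_fraction, "contamination_fraction")
  queries <- sprintf("q%05d", seq_len(n_queries))
  in_sp <- sprintf("VirSp%02d", 1:5)
  out_sp <- sprintf("FunSp%02d", 1:5)

  rows <- with_seed(seed, {
    n_cont <- round(n_queries * contamination_fraction)
    cont <- rep(FALSE, n_queries)
    if (n_cont > 0L) cont[sample.int(n_queries, n_cont)] <- TRUE
    out <- vector("list", n_queries)
    for (i in seq_len(n_queries)) {
      top <- runif(1, 100, 500)
      subj <- function(sp) sprintf("%s|p%05d", sample(sp, 1L), sample.int(99999L, 1L))
      if (cont[i]) {
        best_in <- top * runif(1, 0.10, 0.90)   # AI >= 0.10 > threshold
        in_scores <- c(best_in, best_in * runif(n_extra_hits, 0.2, 0.99))
        out_scores <- c(top, top * runif(n_extra_hits, 0.2, 0.99))
      } else {
        best_out <- top * runif(1, 0.10, 0.94)  # nbsO < 0.95 => AI <= -0.06
        in_scores <- c(top, top * runif(n_extra_hits, 0.2, 0.99))
        out_scores <- c(best_out, best_out * runif(n_extra_hits, 0.2, 0.99))
      }
      out[[i]] <- tibble(
        query = queries[i],
        subject = c(vapply(seq_along(in_scores), function(j) subj(in_sp), character(1)),
                    vapply(seq_along(out_scores), function(j) subj(out_sp), character(1))),
        bitscore = c(in_scores, out_scores))
    }
    list(hits = bind_rows(out), cont = cont)
  })

  list(
    hits = rows$hits,
    lineage_map = tibble(
      subject = c(in_sp, out_sp),
      group = c(rep("Viridiplantae", length(in_sp)),
                rep("Fungi", length(out_sp)))),
    truth = tibble(query = queries, contaminant = rows$cont)
  )
}

#' Simulate a gene-to-term annotation map with injected enrichment
#'
#' Assigns background terms to genes at a base rate; the designated
#' enriched terms are assigned to members of the target set at `base_rate *
#' effect` (capped at 1) and to other genes at the base rate. With `effect
#' = 1` the construction is a pure null. The enriched term ids are recorded
#' as truth.
#'
#' @param genes Character vector of gene ids.
#' @param n_terms Total number of terms.
#' @param enriched_term_count Number of terms constructed as enriched.
#' @param target_set Genes in which the enriched terms are over-assigned
#'   (must be a subset of `genes`).
#' @param effect Rate multiplier for enriched terms in the target set
#'   (>= 1).
#' @param base_rate Background per-gene assignment probability per term.
#' @param seed Integer seed.
#' @return A list with `annotations` (tibble gene, term), `enriched_terms`
#'   (character truth), and `params`.
#' @export
assign_annotations <- function(genes, n_terms = 100L, enriched_term_count = 5L,
                               target_set = character(0), effect = 8,
                               base_rate = 0.05, seed = 1L) {
  if (length(setdiff(target_set, genes)))
    abort("`target_set` must be a subset of `genes`.")
  if (effect < 1) abort("`effect` must be >= 1.")
  assert_prob(base_rate, "base_rate")
  terms <- sprintf("T%03d", seq_len(n_terms))
  is_target <- genes %in% target_set

  ann <- with_seed(seed, {
    enriched <- if (enriched_term_count > 0L)
      sort(sample(terms, enriched_term_count)) else character(0)
    out <- vector("list", n_terms)
    for (t in seq_len(n_terms)) {
      p <- rep(base_rate, length(genes))
      if (terms[t] %in% enriched)
        p[is_target] <- min(1, base_rate * effect)
      hit <- runif(length(genes)) < p
      if (any(hit)) out[[t]] <- tibble(gene = genes[hit], term = terms[t])
    }
    list(tbl = bind_rows(out), enriched = enriched)
  })

  list(annotations = arrange(ann$tbl, .data$gene, .data$term),
       enriched_terms = ann$enriched,
       params = list(n_terms = n_terms,
                     enriched_term_count = enriched_term_count,
                     effect = effect, base_rate = base_rate, seed = seed))
}

#' Write a simulation bundle to disk
#'
#' Emits exactly the formats the readers consume: the count matrix TSV, one
#' Newick gene tree per orthogroup, the hit and lineage TSVs, the
#' annotation TSV, plus `truth_history.tsv` and `truth_labels.tsv`
#' recording the ground truth. Every file header records seed and
#' parameters.
#'
#' @param sim A `gene_content_sim`.
#' @param dir Output directory.
#' @param gene_trees Optional list from [simulate_gene_trees()].
#' @param hit_sim Optional list from [simulate_hit_table()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, gene_trees = NULL, hit_sim = NULL) {
  stopifnot(inherits(sim, "gene_content_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- sim$history$params
  write_count_matrix(sim$counts, file.path(dir, "gene_counts.tsv"), p)
  write_species_tree(sim$tree, file.path(dir, "species_tree.nwk"))
  write_tsv_provenance(
    left_join(sim$history$gains,
              count(sim$history$events, .data$orthogroup, .data$type),
              by = "orthogroup"),
    file.path(dir, "truth_history.tsv"), p)
  if (!is.null(gene_trees)) {
    gt_dir <- file.path(dir, "gene_trees")
    dir.create(gt_dir, showWarnings = FALSE)
    for (og in names(gene_trees))
      writeLines(ape::write.tree(gene_trees[[og]]$phylo),
                 file.path(gt_dir, paste0(og, ".nwk")), useBytes = TRUE)
  }
  if (!is.null(hit_sim)) {
    readr::write_tsv(hit_sim$hits, file.path(dir, "hits.tsv"),
                     col_names = FALSE, eol = "\n")
    readr::write_tsv(hit_sim$lineage_map, file.path(dir, "lineage_map.tsv"),
                     col_names = FALSE, eol = "\n")
    write_tsv_provenance(hit_sim$truth, file.path(dir, "truth_labels.tsv"), p)
  }
  invisible(dir)
}
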