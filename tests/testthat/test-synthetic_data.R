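tr8 <- parse_species_tree("(((A,B),(C,D)),((E,F),(G,H)));")

test_that("no-event limit: root gain, zero loss and duplication", {
  sim <- simulate_gene_content(tr8, 30, p_loss = 0, p_dup = 0,
                               root_gain_fraction = 1, seed = 1)
  expect_true(all(sim$history$gains$gain_node == tr8$root))
  mat <- as.matrix(sim$counts[, tr8$leaves])
  expect_true(all(mat == 1L))
  expect_equal(nrow(sim$history$events), 0L)
})

test_that("certain loss: p_loss = 1 with root gain empties every leaf", {
  sim <- simulate_gene_content(tr8, 10, p_loss = 1, p_dup = 0,
                               root_gain_fraction = 1, seed = 2)
  expect_true(all(as.matrix(sim$counts[, tr8$leaves]) == 0L))
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_gene_content(tr8, 100, p_loss = 0.1, p_dup = 0.1, seed = 42)
  s2 <- simulate_gene_content(tr8, 100, p_loss = 0.1, p_dup = 0.1, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$history, s2$history)
  s3 <- simulate_gene_content(tr8, 100, p_loss = 0.1, p_dup = 0.1, seed = 43)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("leaf counts replayed from the event log equal the emitted matrix", {
  for (seed in c(3, 4, 5)) {
    sim <- simulate_gene_content(tr8, 50, p_loss = 0.1, p_dup = 0.2,
                                 seed = seed)
    # replay: walk each orthogroup's events independently of the generator
    states <- sim$history$states
    events <- sim$history$events
    gains <- sim$history$gains
    for (og in gains$orthogroup) {
      cnt <- setNames(rep(0L, length(tr8$preorder)), tr8$preorder)
      gain <- gains$gain_node[gains$orthogroup == og]
      cnt[gain] <- 1L
      ev <- events[events$orthogroup == og, ]
      for (v in tr8$preorder) {
        p <- tr8$parent[[v]]
        if (v == gain || is.na(p) || cnt[[p]] == 0L) next
        if (!st_mrca_for_test(tr8, c(gain, v)) == gain) next
        row <- ev[ev$node == v, ]
        cnt[v] <- if (nrow(row) && row$type[1] == "loss") 0L
        else cnt[[p]] + if (nrow(row)) sum(row$n[row$type == "duplication"]) else 0L
      }
      emitted <- unlist(sim$counts[sim$counts$orthogroup == og, tr8$leaves])
      expect_equal(unname(cnt[tr8$leaves]), unname(emitted), info = og)
      truth_states <- states$count[states$orthogroup == og]
      expect_equal(unname(cnt[states$node[states$orthogroup == og]]),
                   truth_states, info = og)
    }
  }
})

test_that("every history has exactly one gain per orthogroup", {
  sim <- simulate_gene_content(tr8, 200, p_loss = 0.2, p_dup = 0.1, seed = 6)
  expect_equal(nrow(sim$history$gains), 200L)
  expect_true(all(!is.na(sim$history$gains$gain_node)))
  # the true state at the gain node is exactly 1
  st <- dplyr::inner_join(sim$history$states,
                          sim$history$gains,
                          by = c("orthogroup", node = "gain_node"))
  expect_true(all(st$count == 1L))
})

test_that("gene trees from a lossless one-duplication history re-detect the event", {
  tr4 <- parse_species_tree("((A,B),(C,D));")
  # hand-built history: gain on the root branch, one duplication on it
  history <- list(
    params = list(),
    gains = tibble::tibble(orthogroup = "OG1", gain_node = "N1"),
    states = NULL,
    events = tibble::tibble(orthogroup = "OG1", node = "N1",
                            type = "duplication", n = 1L))
  gts <- simulate_gene_trees(history, tr4)
  gt <- gts[["OG1"]]
  expect_equal(sum(gt$nodes$is_leaf), 8L)
  cls <- classify_gene_tree_nodes(gt, tr4)
  dups <- cls[cls$event == "duplication", ]
  expect_equal(nrow(dups), 1L)
  expect_equal(dups$support, 1.0)
  expect_equal(dups$species_node, "N1")
})

test_that("gene trees without duplications are congruent with the species tree", {
  sim <- simulate_gene_content(tr8, 20, p_loss = 0, p_dup = 0,
                               root_gain_fraction = 1, seed = 7)
  gts <- suppressMessages(simulate_gene_trees(sim))
  expect_length(gts, 20L)
  for (gt in gts[1:3]) {
    expect_equal(sum(gt$nodes$is_leaf), 8L)
    cls <- classify_gene_tree_nodes(gt, tr8)
    expect_true(all(cls$event == "speciation"))
    # leaf species sets match the species tree clades exactly
    expect_setequal(gt$nodes$species[gt$nodes$is_leaf], tr8$leaves)
  }
})

test_that("loss pruning removes whole clades from the gene-tree leaf set", {
  history <- list(
    params = list(),
    gains = tibble::tibble(orthogroup = "OG1", gain_node = "N1"),
    states = NULL,
    events = tibble::tibble(orthogroup = "OG1", node = "N2",
                            type = "loss", n = 1L))
  gts <- simulate_gene_trees(history, tr8)  # N2 subtends A,B,C,D
  gt <- gts[["OG1"]]
  expect_setequal(gt$nodes$species[gt$nodes$is_leaf], c("E", "F", "G", "H"))
})

test_that("Dollo gain-node recovery is monotone non-increasing in p_loss", {
  rates <- vapply(c(0, 0.05, 0.15, 0.3), function(pl) {
    sim <- simulate_gene_content(tr8, 100, p_loss = pl, p_dup = 0,
                                 root_gain_fraction = 0.5, seed = 11)
    rec <- reconstruct_gene_content(sim$counts, tr8)
    joined <- dplyr::inner_join(rec$dollo, sim$history$gains,
                                by = "orthogroup")
    mean(joined$gain_node.x == joined$gain_node.y, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rates) <= 1e-9))
  expect_equal(rates[1], 1.0)
})

test_that("hit-table and annotation generators honor their guarantees", {
  hs0 <- simulate_hit_table(n_queries = 40, contamination_fraction = 0,
                            seed = 13)
  screen0 <- hs0$hits |> normalize_bit_scores() |>
    compute_alien_index(hs0$lineage_map) |> filter_contaminants()
  expect_equal(sum(screen0$flagged), 0L)

  hs1 <- simulate_hit_table(n_queries = 40, contamination_fraction = 1,
                            seed = 13)
  screen1 <- hs1$hits |> normalize_bit_scores() |>
    compute_alien_index(hs1$lineage_map) |> filter_contaminants()
  expect_equal(sum(screen1$flagged), 40L)

  genes <- sprintf("g%03d", 1:200)
  ann <- assign_annotations(genes, n_terms = 20, enriched_term_count = 2,
                            target_set = genes[1:20], effect = 10, seed = 14)
  expect_length(ann$enriched_terms, 2L)
  expect_true(all(ann$annotations$term %in% sprintf("T%03d", 1:20)))
  # deterministic under seed
  ann2 <- assign_annotations(genes, n_terms = 20, enriched_term_count = 2,
                             target_set = genes[1:20], effect = 10, seed = 14)
  expect_identical(ann$annotations, ann2$annotations)
})
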