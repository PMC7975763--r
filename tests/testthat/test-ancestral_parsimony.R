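tr4 <- parse_species_tree("((A,B),(C,D));")

test_that("Dollo places the gain at the MRCA and counts minimal losses", {
  all_present <- dollo_reconstruct(c(A = TRUE, B = TRUE, C = TRUE, D = TRUE), tr4)
  expect_equal(all_present$gain_node, "N1")
  expect_equal(all_present$n_losses, 0L)

  single <- dollo_reconstruct(c(A = TRUE, B = FALSE, C = FALSE, D = FALSE), tr4)
  expect_equal(single$gain_node, "A")
  expect_equal(single$n_losses, 0L)

  split <- dollo_reconstruct(c(A = TRUE, B = FALSE, C = TRUE, D = FALSE), tr4)
  expect_equal(split$gain_node, "N1")
  expect_setequal(split$loss_edges, c("B", "D"))
  # exhaustive single-gain enumeration agrees
  oracle <- dollo_brute(c(A = TRUE, B = FALSE, C = TRUE, D = FALSE), tr4)
  expect_equal(split$n_losses, oracle$n_losses)
  expect_equal(split$gain_node, oracle$gain_node)

  none <- dollo_reconstruct(c(A = FALSE, B = FALSE, C = FALSE, D = FALSE), tr4)
  expect_true(is.na(none$gain_node))
  expect_false(any(none$presence))

  expect_error(dollo_reconstruct(c(A = TRUE), tr4), "missing leaves")
})

test_that("Dollo equals brute-force enumeration on random trees and profiles", {
  set.seed(2024)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    tr <- random_species_tree(n)
    presence <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), tr$leaves)
    if (!any(presence)) presence[sample(n, 1)] <- TRUE
    d <- dollo_reconstruct(presence, tr)
    o <- dollo_brute(presence, tr)
    expect_equal(d$n_losses, o$n_losses)
    expect_equal(d$gain_node, o$gain_node)
    expect_equal(d$gain_node, st_mrca_for_test(tr, names(presence)[presence]))
  }
})

test_that("Wagner DP reproduces its worked examples and the tie rule", {
  flat <- wagner_reconstruct(c(A = 3, B = 3, C = 3, D = 3), tr4)
  expect_equal(unname(flat$state), rep(3L, 7))
  expect_equal(flat$cost, 0)

  ex <- wagner_reconstruct(c(A = 2, B = 0, C = 2, D = 2), tr4)
  expect_equal(ex$cost, 2)
  expect_equal(ex$state[["N1"]], 2L)
  expect_equal(ex$state[["N2"]], 2L)
  expect_equal(ex$state[["N3"]], 2L)

  # two-leaf cherry: every root state in 0..4 costs 4; tie rule picks 0
  tr2 <- parse_species_tree("(A,B);")
  tie <- wagner_reconstruct(c(A = 0, B = 4), tr2)
  expect_equal(tie$cost, 4)
  expect_equal(tie$state[[tr2$root]], 0L)
})

test_that("Wagner DP cost equals exhaustive enumeration on random instances", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    tr <- random_species_tree(n)
    counts <- setNames(sample(0:3, n, replace = TRUE), tr$leaves)
    w <- wagner_reconstruct(counts, tr)
    expect_equal(w$cost, wagner_brute(counts, tr))
    # the returned assignment achieves the returned cost
    achieved <- sum(vapply(tr$preorder, function(v) {
      p <- tr$parent[[v]]
      if (is.na(p)) 0L else abs(w$state[[p]] - w$state[[v]])
    }, integer(1)))
    expect_equal(achieved, w$cost)
  }
})

test_that("leaf counts above max_state are capped with a warning", {
  expect_warning(w <- wagner_reconstruct(c(A = 100, B = 1, C = 1, D = 1), tr4,
                                         max_state = 8),
                 "Capping")
  expect_equal(w$state[["A"]], 8L)
})

test_that("event definitions: gain vs expansion are mutually exclusive", {
  tr2 <- parse_species_tree("(A,B);")
  # parent (root) single copy, child A three copies: expansion at A, no gain
  states <- tibble::tibble(
    orthogroup = "OG1",
    node = c("N1", "A", "B"),
    dollo_present = TRUE,
    wagner_state = c(1L, 3L, 1L))
  ev <- orthogroup_events(states, tr2)
  a_ev <- ev[ev$node == "A", ]
  expect_equal(a_ev$event, "expansion")
  # parent 0, child 2: gain only, no expansion
  states2 <- tibble::tibble(
    orthogroup = "OG1",
    node = c("N1", "A", "B"),
    dollo_present = c(FALSE, TRUE, FALSE),
    wagner_state = c(0L, 2L, 0L))
  ev2 <- orthogroup_events(states2, tr2)
  a_ev2 <- ev2[ev2$node == "A" & ev2$method == "wagner", ]
  expect_equal(a_ev2$event, "gain")
})

test_that("Dollo charges exactly one gain per orthogroup present anywhere", {
  set.seed(5)
  tr <- random_species_tree(6)
  cm <- tibble::as_tibble(c(
    list(orthogroup = sprintf("OG%02d", 1:40)),
    setNames(lapply(tr$leaves, function(s) sample(0:2, 40, replace = TRUE)),
             tr$leaves)))
  rec <- reconstruct_gene_content(cm, tr)
  gains <- rec$events |>
    dplyr::filter(method == "dollo", event == "gain") |>
    dplyr::count(orthogroup)
  present_any <- cm$orthogroup[rowSums(cm[tr$leaves]) > 0]
  expect_setequal(gains$orthogroup, present_any)
  expect_true(all(gains$n == 1L))
})

test_that("on binary profiles Wagner's gain+loss cost never exceeds Dollo's", {
  set.seed(31)
  for (i in 1:20) {
    tr <- random_species_tree(sample(4:7, 1))
    presence <- setNames(sample(c(TRUE, FALSE), length(tr$leaves),
                                replace = TRUE), tr$leaves)
    if (!any(presence)) next
    d <- dollo_reconstruct(presence, tr)
    w <- wagner_reconstruct(setNames(as.integer(presence), names(presence)), tr)
    dollo_cost <- 1L + d$n_losses  # one gain plus its losses
    expect_lte(w$cost, dollo_cost)
  }
})

test_that("summary totals satisfy the per-node checksum identity", {
  set.seed(99)
  tr <- random_species_tree(6)
  cm <- tibble::as_tibble(c(
    list(orthogroup = sprintf("OG%03d", 1:200)),
    setNames(lapply(tr$leaves, function(s) sample(0:3, 200, replace = TRUE)),
             tr$leaves)))
  rec <- reconstruct_gene_content(cm, tr)
  s <- rec$summary
  parent <- tr$parent
  for (i in seq_len(nrow(s))) {
    p <- parent[[s$node[i]]]
    if (is.na(p)) {
      expect_equal(s$dollo_total[i], s$dollo_gains[i])
      expect_equal(s$wagner_total[i], s$wagner_gains[i])
    } else {
      j <- match(p, s$node)
      expect_equal(s$dollo_total[i],
                   s$dollo_total[j] + s$dollo_gains[i] - s$dollo_losses[i])
      expect_equal(s$wagner_total[i],
                   s$wagner_total[j] + s$wagner_gains[i] - s$wagner_losses[i])
    }
  }
})

test_that("orthogroup order does not affect node tallies; empty matrix gives zeros", {
  tr <- tr4
  cm <- tibble::tibble(orthogroup = c("OG1", "OG2", "OG3"),
                       A = c(1L, 0L, 2L), B = c(1L, 2L, 0L),
                       C = c(0L, 2L, 1L), D = c(0L, 0L, 1L))
  r1 <- reconstruct_gene_content(cm, tr)
  r2 <- reconstruct_gene_content(cm[c(3, 1, 2), ], tr)
  expect_equal(r1$node_events, r2$node_events)

  empty <- reconstruct_gene_content(cm[0, ], tr)
  expect_true(all(empty$node_events$dollo_gains == 0))
  expect_true(all(empty$node_events$expansions == 0))
})
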