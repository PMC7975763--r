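test_that("hypergeometric tail matches direct binomial-coefficient arithmetic", {
  # N=20, K=5, n=6, k=4: p = [C(5,4)C(15,2) + C(5,5)C(15,1)] / C(20,6)
  expected <- (choose(5, 4) * choose(15, 2) + choose(5, 5) * choose(15, 1)) /
    choose(20, 6)
  genes <- sprintf("g%02d", 1:20)
  annot <- tibble::tibble(gene = genes[1:5], term = "T1")
  study <- c(genes[1:4], genes[6:7])  # 4 of the 5 T1 genes among 6 study genes
  # population restricted to annotated genes would shrink N; pad annotations
  # so every population gene carries some term
  annot <- dplyr::bind_rows(annot, tibble::tibble(gene = genes, term = "T0"))
  res <- hypergeom_enrich(study, genes, annot)
  expect_equal(res$p_raw[res$term == "T1"], expected, tolerance = 1e-12)
  expect_equal(res$k[res$term == "T1"], 4L)
  expect_equal(res$N[res$term == "T1"], 20L)

  # the certain event: k = n = K = N
  res2 <- hypergeom_enrich(genes, genes, tibble::tibble(gene = genes, term = "T1"))
  expect_equal(res2$p_raw, 1.0)

  # study with no annotated genes: empty result
  res3 <- hypergeom_enrich("g99", c(genes, "g99"),
                           tibble::tibble(gene = genes, term = "T1"))
  expect_equal(nrow(res3), 0L)

  expect_error(hypergeom_enrich("zz", genes, annot), "not in population")
})

test_that("random hypergeometric configurations match the oracle to 1e-12", {
  set.seed(42)
  for (i in 1:100) {
    N <- sample(10:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(max(0, n + K - N):min(K, n), 1)
    if (k < 1) k <- min(K, n)
    p_pkg <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_brute <- hyper_tail_brute(N, K, n, k)
    expect_equal(p_pkg, p_brute, tolerance = 1e-12)
  }
})

test_that("enrichment p-value is monotone decreasing in k", {
  p <- vapply(1:6, function(k) phyper(k - 1, 8, 42, 10, lower.tail = FALSE),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("BH adjustment matches the textbook step-up on fixed and random input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(7)
  for (i in 1:100) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH is order invariant and fixes its invariant sequences", {
  set.seed(8)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # constant p-vectors are fixed points of the step-up procedure
  expect_equal(bh_adjust(rep(0.2, 15)), rep(0.2, 15))
  # re-adjusting can only move values toward (never past) the original raw p
  adj <- sort(bh_adjust(p))
  expect_true(all(bh_adjust(adj) >= adj))
})

test_that("term networks threshold Jaccard overlap and cluster components", {
  mk <- function(term, genes, p_adj)
    tibble::tibble(term = term, term_name = NA_character_,
                   k = length(genes), n = 10L, K = 5L, N = 50L,
                   p_raw = p_adj, p_adj = p_adj,
                   study_genes = list(genes))
  res <- dplyr::bind_rows(
    mk("T1", c("a", "b", "c"), 0.001),
    mk("T2", c("a", "b", "c"), 0.002),   # identical to T1: overlap 1
    mk("T3", c("x", "y"), 0.003),        # disjoint from all
    mk("T4", c("a", "z"), 0.004),        # overlap with T1: 1/4 = 0.25
    mk("T5", c("q"), 0.9))               # not significant
  net <- build_term_network(res, padj_cutoff = 0.05, overlap_cutoff = 0.2)
  expect_setequal(net$nodes$term, c("T1", "T2", "T3", "T4"))
  e <- net$edges
  key <- paste(pmin(e$term_a, e$term_b), pmax(e$term_a, e$term_b))
  expect_setequal(key, c("T1 T2", "T1 T4", "T2 T4"))
  expect_equal(e$overlap[key == "T1 T2"], 1.0)
  expect_equal(e$overlap[key == "T1 T4"], 0.25)
  # clusters: {T1,T2,T4} together, T3 a singleton
  cl <- setNames(net$nodes$cluster, net$nodes$term)
  expect_equal(cl[["T1"]], cl[["T2"]])
  expect_equal(cl[["T1"]], cl[["T4"]])
  expect_false(cl[["T3"]] == cl[["T1"]])

  # disjoint significant terms: two singleton clusters, no edges
  net2 <- build_term_network(dplyr::bind_rows(
    mk("TA", c("a"), 0.01), mk("TB", c("b"), 0.01)))
  expect_equal(nrow(net2$edges), 0L)
  expect_equal(length(unique(net2$nodes$cluster)), 2L)
})

test_that("injected enrichment is recovered and the null stays controlled", {
  genes <- sprintf("g%04d", 1:1000)
  target <- genes[1:50]
  ann <- assign_annotations(genes, n_terms = 100, enriched_term_count = 5,
                            target_set = target, effect = 8,
                            base_rate = 0.05, seed = 99)
  res <- hypergeom_enrich(target, genes, ann$annotations)
  hits <- res$term[res$p_adj < 0.05]
  recall <- mean(ann$enriched_terms %in% hits)
  expect_gte(recall, 0.8)

  # null construction: effect = 1 gives (near) no discoveries under BH
  fp <- vapply(1:10, function(i) {
    null_ann <- assign_annotations(genes, n_terms = 100,
                                   enriched_term_count = 0,
                                   target_set = target, effect = 1,
                                   base_rate = 0.05, seed = 1000 + i)
    nr <- hypergeom_enrich(target, genes, null_ann$annotations)
    sum(nr$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(fp), 0.1)
})
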