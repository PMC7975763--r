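mk_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    query = vapply(rows, `[[`, character(1), 1),
    subject = vapply(rows, `[[`, character(1), 2),
    bitscore = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)))
}

lineage <- tibble::tibble(subject = c("plantX", "fungusY", "VirSp01", "FunSp01"),
                          group = c("Viridiplantae", "Fungi",
                                    "Viridiplantae", "Fungi"))

test_that("bit-score normalization divides by the per-query maximum", {
  h <- mk_hits(c("q", "q", 400), c("q", "plantX", 200), c("q", "fungusY", 100))
  n1 <- normalize_bit_scores(h, exclude_self = TRUE)
  expect_equal(n1$nbs[n1$subject == "plantX"], 1.0)
  expect_equal(n1$nbs[n1$subject == "fungusY"], 0.5)
  n2 <- normalize_bit_scores(h, exclude_self = FALSE)
  expect_equal(sort(n2$nbs), c(0.25, 0.5, 1.0))

  single <- normalize_bit_scores(mk_hits(c("q", "plantX", 77)))
  expect_equal(single$nbs, 1.0)

  expect_warning(
    dropped <- normalize_bit_scores(mk_hits(c("q", "q", 10))),
    "self-hits")
  expect_equal(nrow(dropped), 0L)
})

test_that("alien index is the best-outgroup minus best-ingroup normalized score", {
  h <- mk_hits(c("q1", "plantX", 30), c("q1", "fungusY", 100),
               c("q2", "plantX", 50))
  rec <- h |> normalize_bit_scores() |> compute_alien_index(lineage)
  expect_equal(rec$ai[rec$query == "q1"], 1.0 - 0.3)
  # no out-group hit: nbsO = 0, AI = -1 (the minimum)
  expect_equal(rec$nbs_outgroup[rec$query == "q2"], 0)
  expect_equal(rec$ai[rec$query == "q2"], -1.0)
  expect_true(all(rec$ai >= -1 & rec$ai <= 1))
})

test_that("alien index matches a per-query max/subtract re-scan on a mixed table", {
  h <- mk_hits(
    c("a", "plantX", 120), c("a", "fungusY", 90), c("a", "mystery1", 300),
    c("b", "fungusY", 80), c("b", "plantX", 80),
    c("c", "mystery2", 55),
    c("d", "plantX", 10), c("d", "fungusY", 40),
    c("e", "fungusY", 10),
    c("f", "plantX", 60), c("f", "plantX", 30))
  rec <- h |> normalize_bit_scores() |> compute_alien_index(lineage)
  # independent brute-force recomputation straight from the raw table,
  # ignoring subjects absent from the lineage map
  mapped <- merge(h, lineage, by = "subject")
  for (q in unique(mapped$query)) {
    sub <- mapped[mapped$query == q, ]
    mx <- max(h$bitscore[h$query == q])  # normalization uses all non-self hits
    nv <- if (any(sub$group == "Viridiplantae"))
      max(sub$bitscore[sub$group == "Viridiplantae"]) / mx else 0
    no <- if (any(sub$group != "Viridiplantae"))
      max(sub$bitscore[sub$group != "Viridiplantae"]) / mx else 0
    expect_equal(rec$ai[rec$query == q], no - nv, info = q)
  }
  # query "c" has only unmapped hits: no record, listed in the report
  expect_false("c" %in% rec$query)
  expect_equal(attr(rec, "ai_report")$unscored_queries, "c")
})

test_that("contaminant flagging is inclusive at the threshold", {
  rec <- tibble::tibble(query = c("x", "y", "z"),
                        nbs_ingroup = c(0.95, 0.950001, 0.5),
                        nbs_outgroup = c(1, 1, 0.4))
  rec$ai <- rec$nbs_outgroup - rec$nbs_ingroup
  screen <- filter_contaminants(rec, threshold = 0.05)
  expect_true(screen$flagged[screen$query == "x"])    # AI exactly 0.05
  expect_false(screen$flagged[screen$query == "y"])   # AI just below
  expect_false(screen$flagged[screen$query == "z"])
  expect_equal(flagged_ids(screen), "x")
  expect_equal(retained_ids(screen), c("y", "z"))
})

test_that("simulated contaminants are recovered exactly at threshold 0.05", {
  hs <- simulate_hit_table(n_queries = 100, contamination_fraction = 0.1,
                           seed = 101)
  screen <- hs$hits |>
    normalize_bit_scores() |>
    compute_alien_index(hs$lineage_map) |>
    filter_contaminants(threshold = 0.05)
  expect_equal(sum(hs$truth$contaminant), 10L)
  expect_setequal(flagged_ids(screen), hs$truth$query[hs$truth$contaminant])
})

test_that("AI is antisymmetric under in/out swap, bounded, and scale invariant", {
  for (i in 1:25) {
    hs <- simulate_hit_table(n_queries = 8, contamination_fraction = 0.5,
                             seed = 9000 + i)
    norm <- normalize_bit_scores(hs$hits)
    a <- compute_alien_index(norm, hs$lineage_map, ingroup = "Viridiplantae")
    b <- compute_alien_index(norm, hs$lineage_map, ingroup = "Fungi")
    expect_equal(a$ai, -b$ai[match(a$query, b$query)])
    expect_true(all(a$ai >= -1 & a$ai <= 1))
    expect_equal(a$ai == 0, a$nbs_ingroup == a$nbs_outgroup)

    # rescaling one query's raw scores leaves its AI unchanged
    q1 <- a$query[1]
    scaled <- hs$hits
    scaled$bitscore[scaled$query == q1] <- scaled$bitscore[scaled$query == q1] * 7.3
    a2 <- scaled |> normalize_bit_scores() |> compute_alien_index(hs$lineage_map)
    expect_equal(a2$ai[a2$query == q1], a$ai[a$query == q1])
  }
})
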