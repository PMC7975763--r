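#' One-sided hypergeometric term enrichment
#'
#' Tests each annotation term for over-representation in a study gene set
#' against a population (background) gene set. For a term annotated to `K`
#' of the `N` annotated population genes and `k` of the `n` annotated study
#' genes, the raw p-value is the exact upper tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Raw p-values are adjusted
#' across all tested terms with the Benjamini-Hochberg step-up procedure.
#'
#' The population is restricted to genes with at least one annotation
#' (unannotated genes are uninformative for term enrichment), and only
#' terms with `k >= 1` are tested. Annotation maps are assumed to be
#' ancestor-propagated already; no ontology graph is consulted.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of background gene ids.
#' @param annot An annotation tibble with columns `gene`, `term` (and
#'   optionally `term_name`); see [read_annotation_map()].
#' @return An `enrichment_result` tibble, sorted by `p_raw` then term id,
#'   with columns `term`, `term_name`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `p_adj`, and a list-column `study_genes`.
#' @examples
#' annot <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
#'                         term = c("T1", "T1", "T1", "T2"))
#' hypergeom_enrich(c("g1", "g2"), paste0("g", 1:4), annot)
#' @export
hypergeom_enrich <- function(study, population, annot) {
  study <- unique(study); population <- unique(population)
  outside <- setdiff(study, population)
  if (length(outside))
    abort(paste0("Validation error: study genes not in population: ",
                 paste(outside, collapse = ", ")))
  if (!all(c("gene", "term") %in% names(annot)))
    abort("`annot` must have columns `gene` and `term`.")
  annot <- filter(annot, .data$gene %in% population)
  pop_annotated <- unique(annot$gene)
  study_annotated <- intersect(study, pop_annotated)
  n_pop <- length(pop_annotated)
  n_study <- length(study_annotated)

  empty <- tibble(term = character(0), term_name = character(0),
                  k = integer(0), n = integer(0), K = integer(0),
                  N = integer(0), p_raw = numeric(0), p_adj = numeric(0),
                  study_genes = list())
  if (n_study == 0L)
    return(structure(empty, class = c("enrichment_result", class(empty))))

  names_tbl <- if ("term_name" %in% names(annot))
    distinct(annot, .data$term, .data$term_name) %>%
      group_by(.data$term) %>% summarise(term_name = .data$term_name[1L],
                                         .groups = "drop")
  else distinct(annot, .data$term) %>% mutate(term_name = NA_character_)

  by_term <- annot %>%
    group_by(.data$term) %>%
    summarise(K = n_distinct(.data$gene),
              study_genes = list(sort(intersect(.data$gene, study_annotated))),
              .groups = "drop") %>%
    mutate(k = lengths(.data$study_genes)) %>%
    filter(.data$k >= 1L)

  res <- by_term %>%
    mutate(n = n_study, N = n_pop,
           # exact upper tail: P(X >= k) = phyper(k - 1, K, N - K, n, lower = FALSE)
           p_raw = phyper(.data$k - 1L, .data$K, n_pop - .data$K, n_study,
                          lower.tail = FALSE)) %>%
    left_join(names_tbl, by = "term") %>%
    arrange(.data$p_raw, .data$term)
  res$p_adj <- bh_adjust(res$p_raw)
  res <- select(res, "term", "term_name", "k", "n", "K", "N",
                "p_raw", "p_adj", "study_genes")
  structure(res, class = c("enrichment_result", class(res)))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment: with the p-values
#' sorted ascending, `p_adj(i) = min over j >= i of p(j) * m / j`, clipped
#' at 1 and returned in the original input order.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values) | p_values <= 0 | p_values > 1))
    abort("Validation error: p-values must lie in (0, 1].")
  p.adjust(p_values, method = "BH")
}

#' Build a term-overlap network from enrichment results
#'
#' Keeps terms significant at `p_adj < padj_cutoff`, connects two terms
#' when the Jaccard similarity of their study gene sets is at least
#' `overlap_cutoff`, and labels connected components as clusters — the
#' standard "enrichment map" view in which mutually overlapping gene sets
#' cluster into functional themes.
#'
#' @param results An `enrichment_result` with populated `study_genes`.
#' @param padj_cutoff Significance cutoff on adjusted p (exclusive).
#' @param overlap_cutoff Minimum Jaccard similarity for an edge
#'   (inclusive).
#' @return A `term_network`: list with `nodes` (term, p_adj, set size,
#'   cluster id) and `edges` (term_a, term_b, overlap).
#' @export
build_term_network <- function(results, padj_cutoff = 0.05,
                               overlap_cutoff = 0.2) {
  assert_prob(padj_cutoff, "padj_cutoff")
  assert_prob(overlap_cutoff, "overlap_cutoff")
  sig <- filter(as_tibble(results), .data$p_adj < padj_cutoff)
  nodes <- tibble(term = sig$term, p_adj = sig$p_adj,
                  size = lengths(sig$study_genes))
  edges <- tibble(term_a = character(0), term_b = character(0),
                  overlap = numeric(0))
  if (nrow(sig) >= 2L) {
    pairs <- utils::combn(seq_len(nrow(sig)), 2L)
    ov <- apply(pairs, 2L, function(ij) {
      a <- sig$study_genes[[ij[1L]]]; b <- sig$study_genes[[ij[2L]]]
      u <- length(union(a, b))
      if (u == 0L) 0 else length(intersect(a, b)) / u
    })
    keep <- ov >= overlap_cutoff
    edges <- tibble(term_a = sig$term[pairs[1L, keep]],
                    term_b = sig$term[pairs[2L, keep]],
                    overlap = ov[keep])
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("term_a", "term_b")], directed = FALSE,
    vertices = nodes$term)
  comp <- if (nrow(nodes)) igraph::components(g)$membership else integer(0)
  nodes$cluster <- unname(comp[nodes$term])
  structure(list(nodes = nodes, edges = edges,
                 padj_cutoff = padj_cutoff, overlap_cutoff = overlap_cutoff),
            class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat(sprintf("<term_network> %d terms, %d edges, %d cluster(s)\n",
              nrow(x$nodes), nrow(x$edges),
              if (nrow(x$nodes)) max(x$nodes$cluster) else 0L))
  invisible(x)
}

#' @describeIn build_term_network Node table of a term network.
#' @param x A `term_network`.
#' @param ... Unused.
#' @export
tidy.term_network <- function(x, ...) x$nodes

#' Plot a term-overlap network
#'
#' Circular layout; point size scales with gene-set size, colour with the
#' adjusted p-value, edges with Jaccard overlap above the cutoff.
#'
#' @param object A `term_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.term_network <- function(object, ...) {
  nodes <- object$nodes
  if (nrow(nodes) == 0L)
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no enriched terms"))
  theta <- seq(0, 2 * pi, length.out = nrow(nodes) + 1L)[seq_len(nrow(nodes))]
  nodes <- mutate(nodes, x = cos(theta), y = sin(theta))
  edges <- object$edges %>%
    left_join(select(nodes, term_a = "term", xa = "x", ya = "y"), by = "term_a") %>%
    left_join(select(nodes, term_b = "term", xb = "x", yb = "y"), by = "term_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$overlap),
      colour = "grey70") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                   colour = .data$p_adj)) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12, label = .data$term),
      size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "adjusted p", size = "genes")
}

#' Write enrichment outputs
#'
#' Writes `enrichment.tsv` (per-term contingency counts and p-values, genes
#' comma-joined) and, when a network is supplied, `term_network.tsv` (edge
#' list with overlap values).
#'
#' @param results An `enrichment_result`.
#' @param dir Output directory.
#' @param network Optional `term_network`.
#' @param prefix File-name prefix (default none).
#' @return `dir`, invisibly.
#' @export
write_enrichment <- function(results, dir, network = NULL, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- as_tibble(results) %>%
    mutate(genes = vapply(.data$study_genes, paste, character(1),
                          collapse = ",")) %>%
    select(-"study_genes")
  write_tsv_provenance(flat, file.path(dir, paste0(prefix, "enrichment.tsv")))
  if (!is.null(network))
    write_tsv_provenance(
      network$edges, file.path(dir, paste0(prefix, "term_network.tsv")),
      params = list(padj_cutoff = network$padj_cutoff,
                    overlap_cutoff = network$overlap_cutoff))
  invisible(dir)
}
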