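#' Normalize bit scores within each query
#'
#' Divides every hit's bit score by the maximum bit score of its query,
#' optionally after removing self-hits (rows whose subject id equals the
#' query id). Normalized scores then lie in `(0, 1]`, with at least one hit
#' per query at exactly 1, which is what bounds the Alien Index to
#' `[-1, 1]`.
#'
#' Queries whose every hit is a self-hit are dropped with a warning; their
#' ids are recorded in the `"dropped_queries"` attribute of the result.
#'
#' @param hits A tibble with columns `query`, `subject`, `bitscore`.
#' @param exclude_self Remove rows with `subject == query` before
#'   normalizing (default `TRUE`).
#' @return The hit tibble with an added `nbs` column (normalized bit score).
#' @examples
#' h <- tibble::tibble(query = "q", subject = c("q", "p", "f"),
#'                     bitscore = c(400, 200, 100))
#' normalize_bit_scores(h)
#' @export
normalize_bit_scores <- function(hits, exclude_self = TRUE) {
  stopifnot(all(c("query", "subject", "bitscore") %in% names(hits)))
  if (any(hits$bitscore <= 0))
    abort("Validation error: bit scores must be positive.")
  dropped <- character(0)
  if (exclude_self) {
    before <- unique(hits$query)
    hits <- filter(hits, .data$subject != .data$query)
    dropped <- setdiff(before, unique(hits$query))
    if (length(dropped))
      warn(paste0("Dropped ", length(dropped),
                  " query(ies) with only self-hits: ",
                  paste(dropped, collapse = ", ")))
  }
  out <- if (nrow(hits) == 0L) mutate(hits, nbs = numeric(0)) else
    hits %>%
      group_by(.data$query) %>%
      mutate(nbs = .data$bitscore / max(.data$bitscore)) %>%
      ungroup()
  attr(out, "dropped_queries") <- dropped
  out
}

# resolve each subject to a lineage group: exact id first, then the prefix
# before the first `sep`
resolve_lineage <- function(subjects, lineage_map, sep = "|") {
  exact <- lineage_map$group[match(subjects, lineage_map$subject)]
  pos <- regexpr(sep, subjects, fixed = TRUE)
  prefix <- ifelse(pos > 0L, substr(subjects, 1L, pos - 1L), subjects)
  by_prefix <- lineage_map$group[match(prefix, lineage_map$subject)]
  ifelse(is.na(exact), by_prefix, exact)
}

#' Compute the Alien Index for each query
#'
#' For each query, `nbs_ingroup` is the maximum normalized bit score over
#' hits to the in-group lineage (0 when there is none), `nbs_outgroup` the
#' maximum over hits to any other mapped lineage (0 when none), and the
#' Alien Index is `ai = nbs_outgroup - nbs_ingroup`, ranging from -1 (only
#' in-group evidence) to +1 (only out-group evidence). Positive values
#' suggest contamination or horizontal transfer.
#'
#' Hits whose subject cannot be resolved to a lineage group are ignored and
#' counted in the `"ai_report"` attribute; queries with no mapped hits at
#' all receive no record (they carry no evidence either way) and are also
#' listed there.
#'
#' @param hits A normalized hit tibble (see [normalize_bit_scores()]; must
#'   contain an `nbs` column).
#' @param lineage_map A tibble with columns `subject`, `group` (full ids or
#'   prefixes; see [read_lineage_map()]).
#' @param ingroup Lineage group counted as "within" (default
#'   `"Viridiplantae"`, i.e. green plants and algae).
#' @param sep Separator used for prefix matching of subject ids.
#' @return A tibble with columns `query`, `nbs_ingroup`, `nbs_outgroup`,
#'   `ai`, carrying an `"ai_report"` attribute (unmapped-hit count and
#'   unscored query ids).
#' @export
compute_alien_index <- function(hits, lineage_map, ingroup = "Viridiplantae",
                                sep = "|") {
  if (!"nbs" %in% names(hits))
    abort("`hits` has no `nbs` column; run normalize_bit_scores() first.")
  hits <- mutate(hits, group = resolve_lineage(.data$subject, lineage_map, sep))
  n_unmapped <- sum(is.na(hits$group))
  all_queries <- unique(hits$query)
  mapped <- filter(hits, !is.na(.data$group))
  records <- mapped %>%
    group_by(.data$query) %>%
    summarise(
      nbs_ingroup = max(c(0, .data$nbs[.data$group == ingroup])),
      nbs_outgroup = max(c(0, .data$nbs[.data$group != ingroup])),
      .groups = "drop") %>%
    mutate(ai = .data$nbs_outgroup - .data$nbs_ingroup) %>%
    arrange(.data$query)
  unscored <- setdiff(all_queries, records$query)
  attr(records, "ai_report") <- list(
    n_unmapped_hits = n_unmapped,
    unscored_queries = unscored,
    ingroup = ingroup)
  records
}

#' Partition queries into retained and possible-contaminant sets
#'
#' Flags every query whose Alien Index is greater than or equal to the
#' threshold (inclusive, default 0.05) as a possible contaminant; all other
#' scored queries are retained. Queries that were never scored (no mapped
#' hits) are retained by default — absence of homology evidence is not
#' evidence of contamination.
#'
#' @param records An Alien Index tibble from [compute_alien_index()].
#' @param threshold Flagging threshold on `ai` (inclusive).
#' @return An `ai_screen` object: the record tibble with an added logical
#'   `flagged` column and screening metadata. Use [glance()] for summary
#'   counts, [retained_ids()] / [flagged_ids()] for the partition.
#' @export
filter_contaminants <- function(records, threshold = 0.05) {
  assert_prob((threshold + 1) / 2, "threshold") # just range sanity: [-1, 1]
  out <- mutate(records, flagged = .data$ai >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "ai_report") <- attr(records, "ai_report")
  class(out) <- c("ai_screen", class(out))
  out
}

#' @describeIn filter_contaminants Queries kept after screening (including
#'   unscored queries, which carry no contamination evidence).
#' @param screen An `ai_screen` object.
#' @export
retained_ids <- function(screen) {
  stopifnot(inherits(screen, "ai_screen"))
  rep <- attr(screen, "ai_report")
  sort(c(screen$query[!screen$flagged], rep$unscored_queries %||% character(0)))
}

#' @describeIn filter_contaminants Queries flagged as possible contaminants.
#' @export
flagged_ids <- function(screen) {
  stopifnot(inherits(screen, "ai_screen"))
  sort(screen$query[screen$flagged])
}

#' @export
glance.ai_screen <- function(x, ...) {
  rep <- attr(x, "ai_report") %||% list()
  tibble(
    n_scored = nrow(x),
    n_flagged = sum(x$flagged),
    n_retained = sum(!x$flagged) + length(rep$unscored_queries %||% character(0)),
    n_unscored = length(rep$unscored_queries %||% character(0)),
    threshold = attr(x, "threshold"),
    ai_min = if (nrow(x)) min(x$ai) else NA_real_,
    ai_median = if (nrow(x)) stats::median(x$ai) else NA_real_,
    ai_max = if (nrow(x)) max(x$ai) else NA_real_
  )
}

#' @export
print.ai_screen <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ai_screen> %d scored queries, %d flagged at AI >= %.3g\n",
              g$n_scored, g$n_flagged, g$threshold))
  NextMethod()
}

#' Plot the Alien Index distribution of a contamination screen
#'
#' Histogram of per-query Alien Index values with the flagging threshold
#' drawn as a dashed line; flagged queries to the right of the line.
#'
#' @param object An `ai_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ai_screen <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ai, fill = .data$flagged)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Alien Index (nbsO - nbsV)", y = "queries",
                  fill = "flagged") +
    ggplot2::theme_minimal()
}

#' Write contamination-screen outputs
#'
#' Writes `ai_scores.tsv` (query, nbs_ingroup, nbs_outgroup, ai, flagged)
#' and the `retained.txt` / `flagged.txt` id lists into a directory.
#'
#' @param screen An `ai_screen` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ai_results <- function(screen, dir) {
  stopifnot(inherits(screen, "ai_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_provenance(as_tibble(screen), file.path(dir, "ai_scores.tsv"),
                       params = list(threshold = attr(screen, "threshold")))
  writeLines(retained_ids(screen), file.path(dir, "retained.txt"), useBytes = TRUE)
  writeLines(flagged_ids(screen), file.path(dir, "flagged.txt"), useBytes = TRUE)
  invisible(dir)
}
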