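#' Read an orthogroup-by-species gene-count matrix
#'
#' Reads the tab-separated gene-count dialect produced by orthology
#' pipelines: the first column holds orthogroup identifiers, the remaining
#' columns one species each, and an optional trailing `Total` column. The
#' `Total` column is always dropped and never trusted — row sums are
#' recomputed from the per-species cells, since such files are frequently
#' hand-edited. Lines starting with `#` are treated as comments.
#'
#' @param file Path to the TSV file, or a literal string containing the
#'   table (anything with a newline is treated as literal content).
#' @return A tibble whose first column is `orthogroup` followed by one
#'   integer column per species.
#' @examples
#' tsv <- "Orthogroup\tA\tB\nOG1\t2\t0\nOG2\t1\t1\n"
#' read_count_matrix(tsv)
#' @export
read_count_matrix <- function(file) {
  df <- readr::read_tsv(file, comment = "#", col_types = readr::cols(
    .default = readr::col_double(),
    readr::col_character()  # first column: orthogroup ids
  ), progress = FALSE)
  if (ncol(df) < 1L) abort("Count matrix has no columns.")
  names(df)[1L] <- "orthogroup"
  if (ncol(df) > 1L && names(df)[ncol(df)] == "Total")
    df <- df[, -ncol(df), drop = FALSE]
  sp <- setdiff(names(df), "orthogroup")
  if (anyDuplicated(sp))
    abort("Validation error: duplicate species columns in count matrix.")
  for (s in sp) {
    v <- df[[s]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      abort(sprintf(
        "Format error: cell is not a non-negative integer at row %d (orthogroup %s), column %s.",
        bad[1L], df$orthogroup[bad[1L]], s))
    df[[s]] <- as.integer(v)
  }
  if (anyDuplicated(df$orthogroup))
    abort(paste0("Validation error: duplicate orthogroup ids: ",
                 paste(unique(df$orthogroup[duplicated(df$orthogroup)]),
                       collapse = ", "), "."))
  as_tibble(df)
}

#' Write a gene-count matrix
#'
#' @param counts A count matrix tibble (`orthogroup` first column).
#' @param path Output path.
#' @param params Named list recorded in the provenance header.
#' @export
write_count_matrix <- function(counts, path, params = list()) {
  write_tsv_provenance(counts, path, params)
}

#' Read a gene-to-term annotation map
#'
#' One term assignment per row: `gene<TAB>term[<TAB>term_name]`. A header
#' row is detected when the first line's first field is literally `gene`.
#' Empty term identifiers are rejected.
#'
#' @param file Path or literal TSV string.
#' @return A tibble with columns `gene`, `term` and (possibly all-`NA`)
#'   `term_name`.
#' @export
read_annotation_map <- function(file) {
  df <- readr::read_tsv(file, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2L) abort("Annotation map needs at least two columns (gene, term).")
  df <- df[, seq_len(min(3L, ncol(df))), drop = FALSE]
  names(df) <- c("gene", "term", "term_name")[seq_len(ncol(df))]
  if (nrow(df) && identical(df$gene[1L], "gene")) df <- df[-1L, , drop = FALSE]
  if (!"term_name" %in% names(df)) df$term_name <- NA_character_
  if (any(is.na(df$term) | !nzchar(df$term)))
    abort("Validation error: empty term identifier in annotation map.")
  if (any(is.na(df$gene) | !nzchar(df$gene)))
    abort("Validation error: empty gene identifier in annotation map.")
  distinct(as_tibble(df))
}

#' Read a tabular homology-hit file
#'
#' Reads the headerless `qseqid<TAB>sseqid<TAB>bitscore` dialect of tabular
#' sequence-search output. Extra columns are ignored; the positions of the
#' three used columns are configurable for other column layouts.
#'
#' @param file Path or literal TSV string.
#' @param columns Named integer vector giving the 1-based positions of
#'   `query`, `subject`, and `bitscore`.
#' @return A tibble with columns `query`, `subject`, `bitscore`.
#' @export
read_hit_table <- function(file, columns = c(query = 1L, subject = 2L, bitscore = 3L)) {
  df <- readr::read_tsv(file, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- max(columns)
  if (ncol(df) < need)
    abort(sprintf("Hit table has %d columns; %d required by the column map.",
                  ncol(df), need))
  out <- tibble(
    query = df[[columns[["query"]]]],
    subject = df[[columns[["subject"]]]],
    bitscore = suppressWarnings(as.numeric(df[[columns[["bitscore"]]]]))
  )
  if (any(is.na(out$bitscore) | out$bitscore <= 0))
    abort("Validation error: bit scores must be positive numbers.")
  out
}

#' Read a subject-to-lineage-group map
#'
#' Two columns, `subject_or_prefix<TAB>group`, headerless. Entries may name a
#' full subject id or the prefix before the species/gene separator; matching
#' in [compute_alien_index()] tries the full id first, then the prefix.
#'
#' @param file Path or literal TSV string.
#' @return A tibble with columns `subject`, `group`.
#' @export
read_lineage_map <- function(file) {
  df <- readr::read_tsv(file, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2L) abort("Lineage map needs two columns (subject, group).")
  out <- tibble(subject = df[[1L]], group = df[[2L]])
  if (nrow(out) && identical(out$subject[1L], "subject")) out <- out[-1L, ]
  out
}

#' Cross-check a count matrix against a species tree
#'
#' Reports, species by species, whether each label occurs in the matrix, in
#' the tree, or both. The pipeline proceeds only on an exact match unless
#' intersection mode is requested via [align_inputs()].
#'
#' @param counts A count-matrix tibble.
#' @param tree A `species_tree`.
#' @return A tibble with columns `species`, `in_matrix`, `in_tree`, plus
#'   attributes `exact_match` (logical) and `intersection` (character).
#' @export
validate_inputs <- function(counts, tree) {
  stopifnot(inherits(tree, "species_tree"))
  msp <- setdiff(names(counts), "orthogroup")
  tsp <- tree$leaves
  all_sp <- sort(union(msp, tsp))
  rep_tbl <- tibble(
    species = all_sp,
    in_matrix = all_sp %in% msp,
    in_tree = all_sp %in% tsp
  )
  inter <- intersect(msp, tsp)
  if (length(inter) == 0L)
    abort("Fatal validation error: no species shared between count matrix and tree.")
  attr(rep_tbl, "exact_match") <- setequal(msp, tsp)
  attr(rep_tbl, "intersection") <- inter
  rep_tbl
}

#' Align a count matrix and species tree for reconstruction
#'
#' In strict mode (default) any species mismatch is fatal. In intersection
#' mode both inputs are restricted to the shared species, and every dropped
#' species is reported via a message.
#'
#' @inheritParams validate_inputs
#' @param strict When `TRUE`, require the matrix species and tree leaves to
#'   match exactly.
#' @return A list with elements `counts` and `tree`, aligned.
#' @export
align_inputs <- function(counts, tree, strict = TRUE) {
  rep_tbl <- validate_inputs(counts, tree)
  if (attr(rep_tbl, "exact_match"))
    return(list(counts = counts, tree = tree, report = rep_tbl))
  if (strict) {
    bad <- rep_tbl$species[!(rep_tbl$in_matrix & rep_tbl$in_tree)]
    abort(paste0("Validation error: species mismatch between matrix and tree (",
                 paste(bad, collapse = ", "),
                 "). Use strict = FALSE to restrict to the intersection."))
  }
  inter <- attr(rep_tbl, "intersection")
  dropped <- setdiff(union(names(counts)[-1L], tree$leaves), inter)
  inform(paste0("Restricting to ", length(inter), " shared species; dropped: ",
                paste(dropped, collapse = ", ")))
  counts2 <- counts[, c("orthogroup", inter), drop = FALSE]
  phy <- ape::keep.tip(tree$phylo, inter)
  list(counts = counts2, tree = new_species_tree(phy), report = rep_tbl)
}
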