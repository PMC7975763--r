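#' Build a pipeline run configuration
#'
#' Collects input paths and thresholds for [run_pipeline()]. Only `tree`,
#' `counts` and `out` are required; the contamination screen, duplication
#' mapping and enrichment stages run only when their inputs are configured.
#' Defaults follow the conventional cutoffs of transcriptome gene-family
#' studies: Alien Index >= 0.05 flags a possible contaminant, duplications
#' need clade support >= 0.50, enrichment reports adjusted p < 0.05.
#'
#' @param tree Path to the species-tree Newick file.
#' @param counts Path to the gene-count TSV.
#' @param out Output directory.
#' @param gene_trees Optional directory of per-orthogroup gene-tree Newick
#'   files.
#' @param hits,lineage_map Optional paths enabling the Alien Index stage.
#' @param annotations,members,focal_species Optional paths/label enabling
#'   per-node enrichment: `annotations` maps gene to term
#'   ([read_annotation_map()]), `members` is a TSV `orthogroup<TAB>gene`
#'   listing the focal species' genes per orthogroup.
#' @param ingroup In-group lineage label for the Alien Index.
#' @param ai_threshold,min_support,padj_cutoff,overlap_cutoff,max_state
#'   Stage thresholds (see the stage functions).
#' @param strict Require exact species match between matrix and tree; when
#'   `FALSE`, restrict both to the intersection.
#' @param seed Integer seed recorded in provenance headers.
#' @return A `run_config` list.
#' @export
run_config <- function(tree, counts, out, gene_trees = NULL, hits = NULL,
                       lineage_map = NULL, annotations = NULL, members = NULL,
                       focal_species = NULL, ingroup = "Viridiplantae",
                       ai_threshold = 0.05, min_support = 0.5,
                       padj_cutoff = 0.05, overlap_cutoff = 0.2,
                       max_state = 64L, strict = TRUE, seed = 1L) {
  assert_prob(min_support, "min_support")
  assert_prob(padj_cutoff, "padj_cutoff")
  assert_prob(overlap_cutoff, "overlap_cutoff")
  if (ai_threshold < -1 || ai_threshold > 1)
    abort("`ai_threshold` must lie in [-1, 1].")
  if (max_state < 1) abort("`max_state` must be >= 1.")
  structure(list(
    tree = tree, counts = counts, out = out, gene_trees = gene_trees,
    hits = hits, lineage_map = lineage_map, annotations = annotations,
    members = members, focal_species = focal_species, ingroup = ingroup,
    ai_threshold = ai_threshold, min_support = min_support,
    padj_cutoff = padj_cutoff, overlap_cutoff = overlap_cutoff,
    max_state = as.integer(max_state), strict = isTRUE(strict) || identical(strict, "TRUE"),
    seed = as.integer(seed)), class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' One `key=value` pair per line; `#` starts a comment. Keys match the
#' arguments of [run_config()].
#'
#' @param path Path to the config file.
#' @param ... Overrides applied after the file is read.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad))
    abort(paste0("Config parse error, expected key=value: ", lines[bad][1L]))
  args <- setNames(
    lapply(kv, function(x) trimws(paste(x[-1L], collapse = "="))),
    vapply(kv, function(x) trimws(x[1L]), character(1)))
  for (num in c("ai_threshold", "min_support", "padj_cutoff",
                "overlap_cutoff", "max_state", "seed"))
    if (num %in% names(args)) args[[num]] <- as.numeric(args[[num]])
  if ("strict" %in% names(args)) args$strict <- toupper(args$strict) %in% c("TRUE", "1", "YES")
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

pipeline_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "orthodyn_stage_error")
  })
}

#' Run the full gene-family dynamics pipeline
#'
#' Executes, in order: the Alien Index contamination screen (when hit and
#' lineage inputs are configured), Dollo + Wagner ancestral reconstruction
#' and event tallying, species-overlap duplication mapping (when a
#' gene-tree directory is configured), and per-node term enrichment of
#' gained/lost gene sets (when annotation inputs are configured). Every
#' stage writes its standard output files with provenance headers into the
#' output directory; a `MANIFEST` lists each file with an MD5 checksum, and
#' `run_report.tsv` aggregates the per-node gains, losses, expansions,
#' contractions and duplication counts in one table. No timestamps are
#' written, so a rerun with the same config is byte-identical.
#'
#' If any stage fails, the error names the stage, partial outputs are
#' retained, and the MANIFEST records the run as incomplete.
#'
#' @param config A `run_config` (or path to a config file).
#' @return A `run_report` object: list with `report` (the per-node table),
#'   `manifest`, `stages` (status per stage), and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  finish <- function(status) {
    files <- setdiff(list.files(out_dir, recursive = TRUE), "MANIFEST")
    sums <- tools::md5sum(file.path(out_dir, files))
    man <- tibble(file = files, md5 = unname(sums))
    lines <- c(paste0("# orthodyn ", orthodyn_version(), " status=", status),
               paste(man$file, man$md5, sep = "\t"))
    writeLines(lines, file.path(out_dir, "MANIFEST"), useBytes = TRUE)
    man
  }
  inform(sprintf(
    "orthodyn pipeline: ai_threshold=%g min_support=%g padj=%g overlap=%g max_state=%d seed=%d",
    config$ai_threshold, config$min_support, config$padj_cutoff,
    config$overlap_cutoff, config$max_state, config$seed))

  tryCatch({
    retained <- NULL
    if (!is.null(config$hits) && !is.null(config$lineage_map)) {
      inform("Stage ai-filter: screening hit table")
      pipeline_stage("ai-filter", {
        hits <- read_hit_table(config$hits)
        lin <- read_lineage_map(config$lineage_map)
        screen <- hits %>%
          normalize_bit_scores() %>%
          compute_alien_index(lin, ingroup = config$ingroup) %>%
          filter_contaminants(threshold = config$ai_threshold)
        write_ai_results(screen, out_dir)
        retained <- retained_ids(screen)
      })
      stages <- c(stages, "ai-filter")
    } else {
      inform("Stage ai-filter: skipped (no hits/lineage_map configured)")
    }

    inform("Stage reconstruct: Dollo + Wagner ancestral content")
    recon <- NULL
    pipeline_stage("reconstruct", {
      tree <- parse_species_tree(
        paste(readLines(config$tree, warn = FALSE), collapse = ""))
      counts <- read_count_matrix(config$counts)
      al <- align_inputs(counts, tree, strict = config$strict)
      recon <- reconstruct_gene_content(al$counts, al$tree,
                                         max_state = config$max_state)
      write_reconstruction(recon, out_dir)
    })
    stages <- c(stages, "reconstruct", "events")

    dup_tally <- NULL
    if (!is.null(config$gene_trees) && dir.exists(config$gene_trees %||% "")) {
      inform("Stage duplications: species-overlap mapping")
      pipeline_stage("duplications", {
        gts <- read_gene_trees(config$gene_trees)
        cls <- bind_rows(lapply(gts, classify_gene_tree_nodes,
                                stree = recon$tree))
        write_duplications(cls, file.path(out_dir, "duplications.tsv"),
                           min_support = config$min_support)
        dup_tally <- tally_duplications(cls, min_support = config$min_support,
                                         tree = recon$tree)
      })
      stages <- c(stages, "duplications")
    } else {
      inform("Stage duplications: skipped (no gene-tree directory configured)")
    }

    if (!is.null(config$annotations) && !is.null(config$members)) {
      inform("Stage enrich: per-node term enrichment of gained/lost sets")
      pipeline_stage("enrich", {
        annot <- read_annotation_map(config$annotations)
        mem <- readr::read_tsv(config$members, comment = "#",
                               col_names = c("orthogroup", "gene"),
                               col_types = "cc", progress = FALSE)
        population <- unique(mem$gene)
        internal <- recon$tree$preorder[!recon$tree$preorder %in% recon$tree$leaves]
        for (nd in internal) for (ev in c("gain", "loss")) {
          ogs <- recon$events %>%
            filter(.data$method == "dollo", .data$node == nd,
                   .data$event == ev) %>%
            pull("orthogroup")
          genes <- unique(mem$gene[mem$orthogroup %in% ogs])
          if (length(genes) == 0L) next
          res <- hypergeom_enrich(genes, population, annot)
          if (nrow(res) == 0L) next
          write_enrichment(res, out_dir,
                           network = build_term_network(
                             res, padj_cutoff = config$padj_cutoff,
                             overlap_cutoff = config$overlap_cutoff),
                           prefix = sprintf("%s_%s_", nd, ev))
        }
      })
      stages <- c(stages, "enrich")
    } else {
      inform("Stage enrich: skipped (no annotations/members configured)")
    }

    report <- recon$summary
    if (!is.null(dup_tally))
      report <- left_join(report,
                          rename(dup_tally, node = "species_node",
                                 duplication_events = "n_events",
                                 duplicated_orthogroups = "n_orthogroups"),
                          by = "node")
    write_tsv_provenance(report, file.path(out_dir, "run_report.tsv"),
                         params = list(seed = config$seed,
                                       stages = paste(stages, collapse = "+")))
    manifest <- finish("COMPLETE")
    structure(list(report = report, manifest = manifest, stages = stages,
                   config = config, recon = recon),
              class = "run_report")
  }, orthodyn_stage_error = function(e) {
    finish("INCOMPLETE")
    stop(e)
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> stages: %s; %d output file(s) in %s\n",
              paste(x$stages, collapse = " -> "), nrow(x$manifest),
              x$config$out))
  print(x$report, n = 10)
  invisible(x)
}

#' @describeIn run_pipeline Per-node report table of a pipeline run.
#' @param x A `run_report`.
#' @param ... Unused.
#' @export
tidy.run_report <- function(x, ...) x$report
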