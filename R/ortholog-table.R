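#' Build the annotated ortholog table
#'
#' The full ortholog-table pipeline: drop per-transcript redundancy,
#' classify relationships from the bipartite graph, compute GOC scores
#' from gene order when annotations are supplied (otherwise any input GOC
#' column is kept), flag high-confidence pairs, and tally relationships
#' per species.
#'
#' @param pairs raw homology pairs (see [read_homology()]).
#' @param annotation_ref,annotation_query optional `gene_annotation`
#'   objects; required to (re)compute GOC and to count species-unique
#'   genes in the tallies.
#' @param compute_goc recompute GOC from gene order (default: yes, when
#'   both annotations are given).
#' @param pid_min,goc_min,wga_min high-confidence thresholds (inclusive).
#' @param goc_window GOC neighborhood half-width.
#' @return An `ortholog_table`: list with `pairs` (canonical columns plus
#'   `pair_id` and `high_confidence`), `tallies`
#'   ([relationship_tallies()]), and the gene universes used.
#' @export
build_ortholog_table <- function(pairs, annotation_ref = NULL,
                                 annotation_query = NULL,
                                 compute_goc = !is.null(annotation_ref) &&
                                   !is.null(annotation_query),
                                 pid_min = 50, goc_min = 75, wga_min = 75,
                                 goc_window = 2) {
  pairs <- deduplicate_transcript_rows(pairs)
  pairs <- classify_relationships(pairs)
  if (compute_goc) {
    if (is.null(annotation_ref) || is.null(annotation_query))
      .oe_stop("both annotations are required to compute GOC scores")
    pairs$goc_score <- goc_scores(pairs, annotation_ref, annotation_query,
                                  window = goc_window)
  }
  if (is.null(pairs$goc_score)) pairs$goc_score <- NA_real_
  if (is.null(pairs$wga_score)) pairs$wga_score <- NA_real_
  pairs$high_confidence <- call_high_confidence(
    pairs$percent_identity, pairs$goc_score, pairs$wga_score,
    pid_min = pid_min, goc_min = goc_min, wga_min = wga_min)
  pairs$pair_id <- paste(pairs$ref_gene_id, pairs$query_gene_id, sep = "|")
  ord <- order(pairs$ref_gene_id, pairs$query_gene_id)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  universe_ref <- if (!is.null(annotation_ref)) annotation_ref$gene_id
  universe_query <- if (!is.null(annotation_query)) annotation_query$gene_id
  structure(list(
    pairs = pairs,
    tallies = relationship_tallies(pairs, universe_ref, universe_query),
    universe_ref = universe_ref,
    universe_query = universe_query,
    params = list(pid_min = pid_min, goc_min = goc_min, wga_min = wga_min,
                  goc_window = goc_window, compute_goc = compute_goc)),
    class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat(sprintf("ortholog_table: %d pairs (%d high-confidence)\n",
              nrow(x$pairs), sum(x$pairs$high_confidence)))
  print(x$tallies)
  invisible(x)
}

#' Write an ortholog table and its tallies as TSV
#'
#' @param x an `ortholog_table`.
#' @param path output TSV for the pair table.
#' @param tally_path optional output TSV for the per-species tallies.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(x, path, tally_path = NULL) {
  cols <- c("ref_gene_id", "ref_gene_name", "query_gene_id",
            "query_gene_name", "homology_type", "percent_identity",
            "goc_score", "wga_score", "high_confidence")
  utils::write.table(x$pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tally_path))
    utils::write.table(x$tallies, tally_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
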