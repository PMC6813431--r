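#' Gene-order conservation score
#'
#' Scores how well a gene's chromosomal neighborhood is conserved around
#' its ortholog.  The two genes upstream and two genes downstream of the
#' target gene are examined; a neighbor counts as conserved when any of
#' its orthologs lies within the two-up/two-down neighborhood of the
#' partner gene.  Each conserved neighbor contributes 25, so the score
#' lies on the lattice `{0, 25, 50, 75, 100}` and 100 means all four
#' neighbors match.  Genes within two positions of a chromosome end have
#' fewer candidate neighbors; absent neighbors count as non-matches, so
#' the denominator stays four.
#'
#' Neighborhoods are formed on the ortholog-bearing gene order: genes with
#' no ortholog in the partner species are skipped when counting the two
#' positions either side, mirroring how gene-order conservation is
#' computed over the orthology map itself.  Genes are ordered by
#' `(chromosome, start, gene_id)`; strand is ignored.
#'
#' @param gene_id target gene in the reference annotation.
#' @param partner_id its ortholog in the query annotation.
#' @param ortholog_map named list mapping each reference gene ID to the
#'   character vector of its query ortholog IDs (see
#'   [ortholog_map_from_pairs()]).
#' @param order_a,order_b the reference and query annotations
#'   (`gene_annotation` data frames or any data frame with `gene_id`,
#'   `chromosome`, `start`).
#' @param window neighborhood half-width in genes (2 in the standard
#'   definition).
#' @return Integer score in `{0, 25, 50, 75, 100}` (for `window = 2`).
#' @export
goc_score <- function(gene_id, partner_id, ortholog_map, order_a, order_b,
                      window = 2) {
  state <- .goc_state(ortholog_map, order_a, order_b, window)
  .goc_one(state, gene_id, partner_id)
}

#' Build a reference-to-query ortholog map from a pair table
#'
#' @param pairs data frame with `ref_gene_id` and `query_gene_id`.
#' @return Named list: reference gene ID -> character vector of query
#'   ortholog IDs.
#' @export
ortholog_map_from_pairs <- function(pairs) {
  split(pairs$query_gene_id, pairs$ref_gene_id)
}

#' GOC scores for every pair in a table
#'
#' @param pairs data frame with `ref_gene_id` and `query_gene_id`.
#' @param annotation_ref,annotation_query the two annotations.
#' @param window neighborhood half-width (2 in the standard definition).
#' @return Numeric vector of scores aligned with `pairs` rows.
#' @export
goc_scores <- function(pairs, annotation_ref, annotation_query, window = 2) {
  state <- .goc_state(ortholog_map_from_pairs(pairs), annotation_ref,
                      annotation_query, window)
  vapply(seq_len(nrow(pairs)), function(i)
    .goc_one(state, pairs$ref_gene_id[i], pairs$query_gene_id[i]),
    numeric(1))
}

# precompute per-chromosome ordered positions restricted to
# ortholog-bearing genes on each side
.goc_state <- function(ortholog_map, order_a, order_b, window = 2) {
  ref_orth <- names(ortholog_map)
  query_orth <- unique(unlist(ortholog_map, use.names = FALSE))
  list(a = .goc_positions(order_a, ref_orth),
       b = .goc_positions(order_b, query_orth),
       map = ortholog_map,
       all_a = order_a$gene_id, all_b = order_b$gene_id,
       window = window)
}

.goc_positions <- function(ann, keep) {
  sub <- ann[ann$gene_id %in% keep, c("gene_id", "chromosome", "start")]
  sub <- sub[order(sub$chromosome, sub$start, sub$gene_id), , drop = FALSE]
  pos <- stats::ave(seq_len(nrow(sub)), sub$chromosome, FUN = seq_along)
  list(gene_id = sub$gene_id, chromosome = sub$chromosome, pos = pos)
}

# genes within `window` order positions of `gene` on its chromosome,
# excluding the gene itself
.goc_neighbors <- function(side, gene, window) {
  i <- match(gene, side$gene_id)
  if (is.na(i)) return(NULL)
  sel <- side$chromosome == side$chromosome[i] &
    abs(side$pos - side$pos[i]) <= window & side$pos != side$pos[i]
  side$gene_id[sel]
}

.goc_one <- function(state, gene_id, partner_id) {
  if (!gene_id %in% state$all_a)
    .oe_stop("lookup error: gene '%s' absent from the reference annotation",
             gene_id)
  if (!partner_id %in% state$all_b)
    .oe_stop("lookup error: gene '%s' absent from the query annotation",
             partner_id)
  nb <- .goc_neighbors(state$a, gene_id, state$window)
  win <- .goc_neighbors(state$b, partner_id, state$window)
  if (is.null(nb) || is.null(win))
    .oe_stop("lookup error: pair (%s, %s) is not in the ortholog map",
             gene_id, partner_id)
  matches <- vapply(nb, function(g)
    any(state$map[[g]] %in% win), logical(1))
  as.numeric(100 / (2 * state$window) * sum(matches))
}
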