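#' Read a homology table
#'
#' Reads a Biomart-style TSV of reference--query gene pairs.  No
#' deduplication happens here: one record per input row, including the
#' per-transcript redundancy of real Biomart exports.
#'
#' @param path TSV path.
#' @param dialect `"biomart"` (the default: verbose Biomart export headers,
#'   matched by pattern, e.g. `"Gene stable ID"`, `"Mouse gene stable ID"`,
#'   `"%id. target ..."`, `"... Gene-order conservation score"`) or
#'   `"plain"` (canonical column names `ref_gene_id`, `query_gene_id`,
#'   `percent_identity`, ...).
#' @param column_map optional named character vector overriding the column
#'   resolution, canonical name -> actual header.
#' @return Data frame with canonical columns `ref_gene_id`,
#'   `ref_gene_name`, `query_gene_id`, `query_gene_name`, `homology_type`,
#'   `percent_identity`, `goc_score`, `wga_score` (missing optional columns
#'   come back as `NA`); unknown extra columns are preserved.
#' @export
read_homology <- function(path, dialect = c("biomart", "plain"),
                          column_map = NULL) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  nm <- names(raw)
  find1 <- function(pattern, exclude = character()) {
    hit <- setdiff(grep(pattern, nm, value = TRUE), exclude)
    if (length(hit) >= 1) hit[1] else NA_character_
  }
  resolved <- if (dialect == "plain") {
    canon <- c("ref_gene_id", "ref_gene_name", "query_gene_id",
               "query_gene_name", "homology_type", "percent_identity",
               "goc_score", "wga_score")
    stats::setNames(ifelse(canon %in% nm, canon, NA_character_), canon)
  } else {
    ref_id <- find1("^Gene stable ID$")
    c(ref_gene_id = ref_id,
      ref_gene_name = find1("^Gene name$"),
      query_gene_id = find1("gene stable ID$", exclude = ref_id),
      query_gene_name = find1(" gene name$"),
      homology_type = find1("homology type$"),
      percent_identity = find1("^%id\\. target"),
      goc_score = find1("Gene-order conservation score$"),
      wga_score = find1("Whole-genome alignment coverage$"))
  }
  if (!is.null(column_map)) resolved[names(column_map)] <- column_map
  required <- c("ref_gene_id", "query_gene_id", "percent_identity")
  for (col in required) {
    if (is.na(resolved[[col]]) || !(resolved[[col]] %in% nm))
      .oe_stop("format error: homology file is missing required column '%s'",
               col)
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    ref_gene_id = as.character(raw[[resolved[["ref_gene_id"]]]]),
                    query_gene_id = as.character(raw[[resolved[["query_gene_id"]]]]))
  grab <- function(col, as_num = FALSE, default = NA) {
    src <- resolved[[col]]
    if (!is.na(src) && src %in% nm) {
      v <- raw[[src]]
      if (as_num) suppressWarnings(as.numeric(v)) else as.character(v)
    } else rep(default, nrow(raw))
  }
  out$ref_gene_name <- grab("ref_gene_name", default = NA_character_)
  out$query_gene_name <- grab("query_gene_name", default = NA_character_)
  out$homology_type <- grab("homology_type", default = NA_character_)
  out$percent_identity <- grab("percent_identity", as_num = TRUE)
  out$goc_score <- grab("goc_score", as_num = TRUE)
  out$wga_score <- grab("wga_score", as_num = TRUE)
  extras <- setdiff(nm, stats::na.omit(resolved))
  for (e in extras) out[[e]] <- raw[[e]]
  out
}

#' Drop per-transcript redundancy from a homology table
#'
#' Biomart exports repeat each gene pair once per reference transcript
#' variant; this keeps the first occurrence of every
#' `(ref_gene_id, query_gene_id)` pair.  Distinct pairs sharing a gene
#' (paralog edges) are all kept.
#'
#' @param pairs data frame with `ref_gene_id` and `query_gene_id`.
#' @return The deduplicated data frame.
#' @export
deduplicate_transcript_rows <- function(pairs) {
  keep <- !duplicated(pairs[, c("ref_gene_id", "query_gene_id")])
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify homology relationships from the bipartite graph
#'
#' Assigns each pair its degree class within its connected component of
#' the reference--query bipartite graph: `one2one` when every gene in the
#' component has degree 1, `many2one` when exactly one species contributes
#' a gene of degree > 1, `many2many` when both do.  Input homology-type
#' annotations are not trusted and are overwritten.
#'
#' @param pairs deduplicated pair data frame.
#' @return `pairs` with the `homology_type` column assigned.
#' @seealso [relationship_tallies()]
#' @export
classify_relationships <- function(pairs) {
  if (nrow(pairs) == 0) {
    pairs$homology_type <- character(0)
    return(pairs)
  }
  if (any(pairs$ref_gene_id == pairs$query_gene_id))
    .oe_stop("structural error: self-loop edges (ref gene equals query gene)")
  if (length(intersect(pairs$ref_gene_id, pairs$query_gene_id)) > 0)
    .oe_stop("structural error: same-species edges (a gene appears on both sides)")
  if (anyDuplicated(pairs[, c("ref_gene_id", "query_gene_id")]))
    .oe_stop("structural error: duplicated pairs; run deduplicate_transcript_rows() first")
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("R|", pairs$ref_gene_id),
               to = paste0("Q|", pairs$query_gene_id)),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  side <- substr(names(memb), 1, 1)
  multi <- deg > 1
  comp_multi_r <- tapply(multi & side == "R", memb, any)
  comp_multi_q <- tapply(multi & side == "Q", memb, any)
  cls <- ifelse(comp_multi_r & comp_multi_q, "many2many",
         ifelse(comp_multi_r | comp_multi_q, "many2one", "one2one"))
  pairs$homology_type <- as.vector(cls[as.character(
    memb[paste0("R|", pairs$ref_gene_id)])])
  pairs
}

#' Per-species relationship tallies
#'
#' Counts distinct genes per species in each homology class, total
#' ortholog genes, species-unique genes (annotation genes without any
#' homology edge) and total protein-coding genes, in the shape of a
#' two-species classification table.
#'
#' @param pairs classified pair data frame (see
#'   [classify_relationships()]).
#' @param universe_ref,universe_query character vectors of all
#'   protein-coding gene IDs per species (e.g. `annotation$gene_id`);
#'   unique-gene and total rows are `NA` when omitted.
#' @return Data frame with one row per species and columns `one2one`,
#'   `many2one`, `many2many`, `total_orthologs`, `unique_genes`,
#'   `total_protein_coding`.
#' @export
relationship_tallies <- function(pairs, universe_ref = NULL,
                                 universe_query = NULL) {
  count_side <- function(ids, universe) {
    per_class <- vapply(c("one2one", "many2one", "many2many"), function(cl)
      length(unique(ids[pairs$homology_type == cl])), integer(1))
    total <- length(unique(ids))
    uniq <- if (is.null(universe)) NA_integer_ else
      length(setdiff(universe, ids))
    tot_pc <- if (is.null(universe)) NA_integer_ else length(unique(universe))
    c(per_class, total_orthologs = total, unique_genes = uniq,
      total_protein_coding = tot_pc)
  }
  out <- rbind(reference = count_side(pairs$ref_gene_id, universe_ref),
               query = count_side(pairs$query_gene_id, universe_query))
  data.frame(species = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Distinct ortholog gene sets per species
#'
#' Collapses query-side redundancy: several reference paralogs mapping to
#' one query gene count once on the query side, so the reference ortholog
#' total is at least the query total.
#'
#' @param pairs classified pair data frame.
#' @return List with `ref_genes`, `query_genes` (character vectors of
#'   distinct gene IDs) and `n_ref`, `n_query`.
#' @export
collapse_query_redundancy <- function(pairs) {
  ref_genes <- unique(pairs$ref_gene_id)
  query_genes <- unique(pairs$query_gene_id)
  list(ref_genes = ref_genes, query_genes = query_genes,
       n_ref = length(ref_genes), n_query = length(query_genes))
}

#' Whole-genome-alignment coverage score for an ortholog pair
#'
#' Per gene, coverage is an exon-weighted mean of exon and intron
#' alignment coverage scaled to 0--100; the pair score is the arithmetic
#' mean of the two genes' scores.
#'
#' @param exon_cov_ref,intron_cov_ref,exon_cov_query,intron_cov_query
#'   alignment coverage fractions in \[0, 1\].
#' @param exon_weight weight on exon coverage, in (0.5, 1\]; exons always
#'   weigh more than introns.
#' @return Pair score in \[0, 100\], vectorized.
#' @export
wga_score <- function(exon_cov_ref, intron_cov_ref, exon_cov_query,
                      intron_cov_query, exon_weight = 0.75) {
  covs <- list(exon_cov_ref, intron_cov_ref, exon_cov_query,
               intron_cov_query)
  for (cv in covs)
    if (any(!is.finite(cv)) || any(cv < 0) || any(cv > 1))
      .oe_stop("domain error: coverages must lie in [0, 1]")
  if (any(exon_weight <= 0.5) || any(exon_weight > 1))
    .oe_stop("domain error: exon_weight must lie in (0.5, 1]")
  per_gene <- function(e, i) 100 * (exon_weight * e + (1 - exon_weight) * i)
  (per_gene(exon_cov_ref, intron_cov_ref) +
     per_gene(exon_cov_query, intron_cov_query)) / 2
}

#' High-confidence ortholog call
#'
#' A pair is high-confidence when percent identity is at least `pid_min`
#' and at least one of the GOC or WGA scores reaches its threshold
#' (inclusive bounds throughout).  A missing score fails its clause; with
#' both scores missing the pair is never high-confidence.
#'
#' @param percent_identity percent identity, 0--100.
#' @param goc_score GOC score in `{0, 25, 50, 75, 100}` or `NA`.
#' @param wga_score WGA score 0--100 or `NA`.
#' @param pid_min,goc_min,wga_min thresholds (defaults 50/75/75).
#' @return Logical vector.
#' @export
call_high_confidence <- function(percent_identity, goc_score = NA,
                                 wga_score = NA, pid_min = 50,
                                 goc_min = 75, wga_min = 75) {
  pid_ok <- !is.na(percent_identity) & percent_identity >= pid_min
  goc_ok <- !is.na(goc_score) & goc_score >= goc_min
  wga_ok <- !is.na(wga_score) & wga_score >= wga_min
  pid_ok & (goc_ok | wga_ok)
}
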