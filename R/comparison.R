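#' Merge expression profiles across species via orthology
#'
#' Joins the two species' differential-expression profiles on the
#' ortholog-pair table: one row per pair with per-cell-type mean RPKM,
#' expressed flags, and per-contrast log2 fold changes and calls for both
#' species.  Pairs lacking expression data in either species are kept but
#' flagged (`analyzed = FALSE`) and excluded from all downstream set
#' analyses; the two species' values are never rescaled onto a common
#' scale.
#'
#' @param ortab an `ortholog_table`.
#' @param profile_ref,profile_query `de_profile` objects for the reference
#'   and query species (see [run_de()]).
#' @return A `merged_ortholog_expression` data frame with columns
#'   `pair_id`, gene IDs/names, `homology_type`, `high_confidence`,
#'   `analyzed`, and per-cell-type columns `ref_mean.<ct>`,
#'   `ref_expressed.<ct>`, `ref_lfc.<ct>`, `ref_call.<ct>`, `ref_fdr`
#'   (likewise `query_*`).  The number of excluded pairs is in
#'   `attr(, "n_excluded")`.
#' @export
merge_expression <- function(ortab, profile_ref, profile_query) {
  if (!inherits(ortab, "ortholog_table"))
    .oe_stop("'ortab' must be an ortholog_table")
  for (p in list(profile_ref, profile_query))
    if (!inherits(p, "de_profile"))
      .oe_stop("profiles must be de_profile objects from run_de()")
  pairs <- ortab$pairs
  if (anyDuplicated(pairs$pair_id))
    .oe_stop("integrity error: duplicated ortholog pairs in the table")
  if (nrow(pairs) == 0)
    warning("empty ortholog table: merged table has no rows")
  out <- pairs[, c("pair_id", "ref_gene_id", "ref_gene_name",
                   "query_gene_id", "query_gene_name", "homology_type",
                   "percent_identity", "goc_score", "wga_score",
                   "high_confidence")]
  ia <- match(out$ref_gene_id, profile_ref$gene_ids)
  ib <- match(out$query_gene_id, profile_query$gene_ids)
  out$analyzed <- !is.na(ia) & !is.na(ib)

  add_side <- function(out, prefix, prof, idx) {
    for (ct in prof$cell_types) {
      out[[paste0(prefix, "_mean.", ct)]] <- prof$mean_rpkm[idx, ct]
      out[[paste0(prefix, "_expressed.", ct)]] <- prof$expressed[idx, ct]
    }
    ctr <- prof$contrasts
    for (ct in setdiff(prof$cell_types, prof$reference)) {
      sub <- ctr[ctr$contrast == ct, ]
      j <- match(out[[paste0(prefix, "_gene_id")]], sub$gene_id)
      out[[paste0(prefix, "_lfc.", ct)]] <- sub$log2fc[j]
      out[[paste0(prefix, "_call.", ct)]] <- sub$call[j]
    }
    out[[paste0(prefix, "_fdr")]] <- prof$fdr_q[idx]
    out
  }
  out <- add_side(out, "ref", profile_ref, ia)
  out <- add_side(out, "query", profile_query, ib)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!out$analyzed)
  attr(out, "cell_types_ref") <- profile_ref$cell_types
  attr(out, "cell_types_query") <- profile_query$cell_types
  attr(out, "reference_ref") <- profile_ref$reference
  attr(out, "reference_query") <- profile_query$reference
  class(out) <- c("merged_ortholog_expression", "data.frame")
  out
}

# resolve a cell-type name to its side ("ref"/"query") in a merged table
.resolve_side <- function(merged, cell_type) {
  in_ref <- cell_type %in% attr(merged, "cell_types_ref")
  in_query <- cell_type %in% attr(merged, "cell_types_query")
  if (!in_ref && !in_query)
    .oe_stop("lookup error: unknown population/cell type '%s'", cell_type)
  if (in_ref) "ref" else "query"
}

#' Three-set Venn partition
#'
#' Exact partition of three gene sets into the seven pairwise-disjoint
#' Venn regions.
#'
#' @param set_a,set_b,set_c character vectors (e.g. ortholog-pair IDs).
#' @param set_names display names for the three sets.
#' @return A `venn3` object: `$regions` is a named list of the seven
#'   exclusive regions (`A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC`),
#'   `$counts` the corresponding sizes, `$set_names` the display names.
#' @export
venn3 <- function(set_a, set_b, set_c, set_names = c("A", "B", "C")) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  c_ <- unique(as.character(set_c))
  all_ids <- unique(c(a, b, c_))
  ina <- all_ids %in% a
  inb <- all_ids %in% b
  inc <- all_ids %in% c_
  regions <- list(
    A = all_ids[ina & !inb & !inc],
    B = all_ids[!ina & inb & !inc],
    C = all_ids[!ina & !inb & inc],
    AB = all_ids[ina & inb & !inc],
    AC = all_ids[ina & !inb & inc],
    BC = all_ids[!ina & inb & inc],
    ABC = all_ids[ina & inb & inc]
  )
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 set_names = set_names),
            class = "venn3")
}

#' @export
print.venn3 <- function(x, ...) {
  cat(sprintf("venn3 of %s:\n", paste(x$set_names, collapse = ", ")))
  print(x$counts)
  invisible(x)
}

#' Pairs commonly regulated across populations
#'
#' Returns the ortholog pairs whose differential-expression call equals
#' `direction` in every listed population's contrast against its species'
#' reference cell type.
#'
#' @param merged a merged table from [merge_expression()].
#' @param direction `"up"` or `"down"`.
#' @param populations cell-type names, each a non-reference cell type of
#'   one of the two species (e.g. `c("nsSC", "PC", "DC")`).
#' @return Character vector of `pair_id`s.
#' @export
common_regulated <- function(merged, direction = c("up", "down"),
                             populations) {
  direction <- match.arg(direction)
  keep <- merged$analyzed
  for (ct in populations) {
    side <- .resolve_side(merged, ct)
    col <- paste0(side, "_call.", ct)
    if (is.null(merged[[col]]))
      .oe_stop("lookup error: '%s' has no contrast against the reference",
               ct)
    keep <- keep & !is.na(merged[[col]]) & merged[[col]] == direction
  }
  merged$pair_id[keep]
}

#' Restrict a pair set to high-confidence orthologs
#'
#' @param pair_ids character vector of `pair_id`s.
#' @param ortab the `ortholog_table` carrying the high-confidence flags.
#' @return The subset of `pair_ids` flagged high-confidence.
#' @export
filter_high_confidence <- function(pair_ids, ortab) {
  idx <- match(pair_ids, ortab$pairs$pair_id)
  if (any(is.na(idx)))
    .oe_stop("integrity error: pairs absent from the ortholog table: %s",
             paste(utils::head(pair_ids[is.na(idx)], 5), collapse = ", "))
  pair_ids[ortab$pairs$high_confidence[idx]]
}

#' Uniquely expressed genes per cell type
#'
#' Assigns each analyzed ortholog pair to a cell type when it is expressed
#' (mean RPKM at or above the cutoff) in that cell type and below cutoff
#' in every other supplied cell type; a pair can belong to at most one
#' set.  Cell types may come from either species.
#'
#' @param merged a merged table from [merge_expression()].
#' @param cell_types cell types to scan (>= 2); default: all cell types of
#'   both species.
#' @param rpkm_cutoff inclusive mean-RPKM cutoff.
#' @param use_expressed_flags use the FDR-combined expressed flags instead
#'   of the plain RPKM cutoff.
#' @return Named list of `pair_id` vectors, one per cell type.
#' @export
unique_expression <- function(merged, cell_types = NULL, rpkm_cutoff = 0.10,
                              use_expressed_flags = FALSE) {
  if (is.null(cell_types))
    cell_types <- c(attr(merged, "cell_types_ref"),
                    attr(merged, "cell_types_query"))
  if (length(cell_types) < 2)
    .oe_stop("configuration error: need at least two cell types")
  sub <- merged[merged$analyzed, , drop = FALSE]
  expr <- vapply(cell_types, function(ct) {
    side <- .resolve_side(merged, ct)
    if (use_expressed_flags)
      sub[[paste0(side, "_expressed.", ct)]]
    else
      sub[[paste0(side, "_mean.", ct)]] >= rpkm_cutoff
  }, logical(nrow(sub)))
  if (nrow(sub) == 1)
    expr <- matrix(expr, nrow = 1, dimnames = list(NULL, cell_types))
  only_one <- rowSums(expr) == 1
  out <- lapply(cell_types, function(ct)
    sub$pair_id[only_one & expr[, ct]])
  stats::setNames(out, cell_types)
}

#' Overlay an annotation list (e.g. transcription factors) on a gene set
#'
#' Filters a result table to the members of an annotation list, matching
#' by gene ID or gene name on either species (the key style is detected
#' automatically), with an optional ranking by descending log2 fold
#' change.
#'
#' @param df data frame of results (e.g. merged-table rows); must carry
#'   the configured ID/name columns.
#' @param annotation character vector of gene IDs or names.
#' @param key `"auto"` (pick whichever of ID/name matches more entries),
#'   `"id"` or `"name"`.
#' @param id_cols,name_cols columns searched for ID/name matches.
#' @param rank_by optional numeric column name to rank by, descending;
#'   ties broken by the first ID column for determinism.
#' @param top_n optional: keep only the first `top_n` ranked rows.
#' @param match_floor warn when the fraction of annotation entries found
#'   in `df` falls below this floor (likely an ID-versus-name mismatch).
#' @return The filtered (and possibly ranked/truncated) data frame.
#' @export
overlay_annotation <- function(df, annotation, key = c("auto", "id", "name"),
                               id_cols = c("ref_gene_id", "query_gene_id"),
                               name_cols = c("ref_gene_name",
                                             "query_gene_name"),
                               rank_by = NULL, top_n = NULL,
                               match_floor = 0.2) {
  key <- match.arg(key)
  annotation <- unique(as.character(annotation))
  if (length(annotation) == 0) return(df[0, , drop = FALSE])
  hit_by <- function(cols) {
    cols <- intersect(cols, names(df))
    if (length(cols) == 0) return(rep(FALSE, nrow(df)))
    Reduce(`|`, lapply(cols, function(cl) df[[cl]] %in% annotation))
  }
  matched_entries <- function(cols) {
    cols <- intersect(cols, names(df))
    mean(annotation %in% unlist(df[cols], use.names = FALSE))
  }
  if (key == "auto")
    key <- if (matched_entries(id_cols) >= matched_entries(name_cols))
      "id" else "name"
  cols <- if (key == "id") id_cols else name_cols
  rate <- matched_entries(cols)
  if (rate < match_floor)
    warning(sprintf(
      "annotation match rate %.1f%% under '%s' keys is below the %.0f%% floor; check ID-versus-name key style",
      100 * rate, key, 100 * match_floor))
  out <- df[hit_by(cols), , drop = FALSE]
  if (!is.null(rank_by)) {
    if (is.null(out[[rank_by]]))
      .oe_stop("lookup error: no column '%s' to rank by", rank_by)
    tie <- intersect(id_cols, names(out))[1]
    out <- out[order(-out[[rank_by]], out[[tie]]), , drop = FALSE]
  }
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
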