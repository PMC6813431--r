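#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: set ID, description, then member gene
#' IDs.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: list with `sets` (named list of member
#'   vectors) and `description` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad) > 0)
    .oe_stop("format error: GMT line %d has fewer than 3 fields", bad[1])
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    .oe_stop("format error: duplicated gene-set IDs in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  structure(list(sets = stats::setNames(sets, ids),
                 description = stats::setNames(
                   vapply(parts, `[[`, character(1), 2), ids)),
            class = "gene_set_collection")
}

#' Upper-tail hypergeometric over-representation test
#'
#' Probability of observing at least the attained overlap between a query
#' gene set and a gene set, drawing without replacement from the universe.
#'
#' @param query character vector of query gene IDs; must lie within the
#'   universe.
#' @param gene_set character vector of set member IDs (members outside the
#'   universe are ignored).
#' @param universe character vector: the background gene universe.
#' @return The upper-tail p-value `P(overlap >= k)`.
#' @export
hypergeom_test <- function(query, gene_set, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  offenders <- setdiff(query, universe)
  if (length(offenders) > 0)
    .oe_stop("composition error: query genes outside the universe: %s%s",
             paste(utils::head(offenders, 5), collapse = ", "),
             if (length(offenders) > 5) ", ..." else "")
  set_in <- intersect(unique(as.character(gene_set)), universe)
  N <- length(universe)
  K <- length(set_in)
  n <- length(query)
  k <- length(intersect(query, set_in))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation of a query set against a collection
#'
#' Hypergeometric p-value per set, BH adjustment across the collection,
#' overlap counts and members; rows are filtered at the FDR cutoff and
#' sorted by (q, p, set ID).
#'
#' @param query character vector of query gene IDs.
#' @param collection a `gene_set_collection` from [read_gmt()] (or a named
#'   list of member vectors).
#' @param universe background gene universe; defaults to the union of the
#'   collection's members and the query.
#' @param fdr_cutoff inclusive BH q-value cutoff; `NULL` disables the
#'   filter.
#' @param p_cutoff optional additional raw p-value filter (exclusive,
#'   `p < p_cutoff`); `NULL` disables it.
#' @return Data frame: `set_id`, `description`, `n_set`, `n_query`,
#'   `n_overlap`, `members`, `p_value`, `fdr_q`.
#' @export
enrich <- function(query, collection, universe = NULL, fdr_cutoff = 0.05,
                   p_cutoff = NULL) {
  sets <- if (inherits(collection, "gene_set_collection"))
    collection$sets else collection
  if (length(sets) == 0)
    .oe_stop("configuration error: empty gene-set collection")
  desc <- if (inherits(collection, "gene_set_collection"))
    collection$description else
      stats::setNames(rep(NA_character_, length(sets)), names(sets))
  query <- unique(as.character(query))
  if (is.null(universe))
    universe <- unique(c(unlist(sets, use.names = FALSE), query))
  p <- vapply(sets, function(s) hypergeom_test(query, s, universe),
              numeric(1))
  overlap <- lapply(sets, function(s)
    sort(intersect(query, intersect(s, universe))))
  out <- data.frame(
    set_id = names(sets),
    description = unname(desc[names(sets)]),
    n_set = vapply(sets, function(s)
      length(intersect(unique(s), universe)), integer(1)),
    n_query = length(query),
    n_overlap = vapply(overlap, length, integer(1)),
    members = vapply(overlap, paste, character(1), collapse = ","),
    p_value = unname(p),
    fdr_q = benjamini_hochberg(unname(p)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$fdr_q, out$p_value, out$set_id), , drop = FALSE]
  if (!is.null(fdr_cutoff)) out <- out[out$fdr_q <= fdr_cutoff, ]
  if (!is.null(p_cutoff)) out <- out[out$p_value < p_cutoff, ]
  rownames(out) <- NULL
  out
}
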