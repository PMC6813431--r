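#' Construct an expression matrix for one species
#'
#' The container for per-cell-type replicate expression values.  Columns
#' are named `"<cell type>:<replicate>"`; values are raw counts (with
#' per-column library sizes) or RPKM.
#'
#' @param values non-negative numeric matrix, genes in rows, columns named
#'   `cell_type:replicate`.
#' @param species species tag (free text).
#' @param cell_types cell types present; derived from column names when
#'   `NULL`.
#' @param reference the reference cell type every contrast is tested
#'   against (the species' hair-cell type in the motivating study).
#' @param value_kind `"counts"` or `"rpkm"`.
#' @param library_sizes named vector of total mapped reads per column;
#'   required when `value_kind = "counts"`.
#' @param gene_ids gene identifiers; default row names of `values`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, species, cell_types = NULL,
                              reference, value_kind = c("counts", "rpkm"),
                              library_sizes = NULL,
                              gene_ids = rownames(values)) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (is.null(gene_ids)) .oe_stop("expression matrix needs gene identifiers")
  if (anyDuplicated(gene_ids))
    .oe_stop("integrity error: duplicated gene identifiers in expression matrix")
  if (is.null(colnames(values)) || !all(grepl(":", colnames(values))))
    .oe_stop("expression columns must be named '<cell type>:<replicate>'")
  if (any(values < 0, na.rm = TRUE))
    .oe_stop("expression values must be non-negative")
  col_ct <- sub(":[^:]*$", "", colnames(values))
  if (is.null(cell_types)) cell_types <- unique(col_ct)
  if (!all(col_ct %in% cell_types))
    .oe_stop("columns reference cell types absent from 'cell_types': %s",
             paste(setdiff(col_ct, cell_types), collapse = ", "))
  if (!reference %in% cell_types)
    .oe_stop("reference cell type '%s' is not among the cell types", reference)
  if (value_kind == "counts") {
    if (is.null(library_sizes))
      .oe_stop("library_sizes are required for count matrices")
    library_sizes <- library_sizes[colnames(values)]
    if (any(is.na(library_sizes)) || any(library_sizes <= 0))
      .oe_stop("library_sizes must be positive for every column")
  }
  rownames(values) <- gene_ids
  structure(list(species = species, gene_ids = gene_ids,
                 cell_types = cell_types, reference = reference,
                 values = values, value_kind = value_kind,
                 library_sizes = library_sizes,
                 column_cell_type = col_ct),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %s, %d genes x %d columns (%s)\n",
              x$species, nrow(x$values), ncol(x$values), x$value_kind))
  cat(sprintf("  cell types: %s (reference: %s)\n",
              paste(x$cell_types, collapse = ", "), x$reference))
  invisible(x)
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' `count * 1e9 / (exonic_length_bp * total_mapped)`.
#'
#' @param count read count(s).
#' @param exonic_length_bp length of the gene's exon-interval union, bp.
#' @param total_mapped total mapped reads in the library.
#' @return RPKM value(s); vectorized with recycling.
#' @export
rpkm <- function(count, exonic_length_bp, total_mapped) {
  if (any(!is.finite(exonic_length_bp)) || any(exonic_length_bp <= 0))
    .oe_stop("domain error: exonic_length_bp must be > 0")
  if (any(!is.finite(total_mapped)) || any(total_mapped <= 0))
    .oe_stop("domain error: total_mapped must be > 0")
  count * 1e9 / (exonic_length_bp * total_mapped)
}

#' Convert a count matrix to RPKM
#'
#' @param x an [expression_matrix()] of counts.
#' @param exonic_lengths named numeric vector of exon-union lengths (bp),
#'   or a `gene_annotation` from which they are taken.
#' @return An [expression_matrix()] with `value_kind = "rpkm"`.
#' @export
to_rpkm <- function(x, exonic_lengths) {
  if (!inherits(x, "expression_matrix")) .oe_stop("'x' must be an expression_matrix")
  if (x$value_kind == "rpkm") return(x)
  if (inherits(exonic_lengths, "gene_annotation"))
    exonic_lengths <- stats::setNames(exonic_lengths$exonic_length,
                                      exonic_lengths$gene_id)
  len <- exonic_lengths[x$gene_ids]
  if (any(is.na(len)))
    .oe_stop("lookup error: no exonic length for genes: %s",
             paste(utils::head(x$gene_ids[is.na(len)], 5), collapse = ", "))
  vals <- x$values
  for (j in seq_len(ncol(vals)))
    vals[, j] <- rpkm(vals[, j], len, x$library_sizes[[j]])
  out <- x
  out$values <- vals
  out$value_kind <- "rpkm"
  out
}

#' Log2 fold change between two mean expressions
#'
#' `log2((mean_alt + pseudocount) / (mean_ref + pseudocount))`; the
#' pseudocount guards zero means.
#'
#' @param mean_alt,mean_ref mean RPKM in the alternative and reference
#'   groups (>= 0).
#' @param pseudocount added to both means before the ratio (RPKM units).
#' @return log2 fold change, vectorized.
#' @export
log2_fold_change <- function(mean_alt, mean_ref, pseudocount = 0.01) {
  log2((mean_alt + pseudocount) / (mean_ref + pseudocount))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1,
#' with the input order preserved.
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    .oe_stop("domain error: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# vectorized per-row one-way ANOVA across groups; returns p-values with the
# documented degenerate conventions (all-equal -> 1, zero residual variance
# with unequal means -> 0)
.oneway_f_rows <- function(x, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(x)
  if (k < 2) .oe_stop("statistics error: need at least two groups")
  ng <- table(groups)
  if (any(ng < 2))
    .oe_stop("statistics error: need >= 2 replicates per group")
  grand <- rowMeans(x)
  sst <- rowSums((x - grand)^2)
  ssb <- 0
  for (lv in levels(groups)) {
    cols <- which(groups == lv)
    m <- rowMeans(x[, cols, drop = FALSE])
    ssb <- ssb + length(cols) * (m - grand)^2
  }
  ssw <- pmax(sst - ssb, 0)
  eps <- 1e-10 * (1 + rowSums(x^2))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  degen <- ssw <= eps
  p[degen & ssb <= eps] <- 1
  p[degen & ssb > eps] <- 0
  p
}

#' Per-gene differential-expression test
#'
#' One-way ANOVA on (optionally log2-transformed) replicate RPKM values;
#' with two groups this is equivalent to the equal-variance two-sample
#' t-test.  Degenerate inputs follow a fixed convention: zero variance with
#' equal means gives `p = 1`, zero within-group variance with unequal means
#' gives `p = 0`.
#'
#' @param values_alt,values_ref replicate RPKM values (>= 2 each).
#' @param ... further replicate groups (for more than two cell types).
#' @param pseudocount RPKM pseudocount used by the log transform.
#' @param log2_transform test on `log2(RPKM + pseudocount)` (the default)
#'   or on the raw scale.
#' @return A two-sided p-value.
#' @export
test_gene <- function(values_alt, values_ref, ..., pseudocount = 0.01,
                      log2_transform = TRUE) {
  groups <- c(list(values_alt, values_ref), list(...))
  if (any(vapply(groups, length, integer(1)) < 2))
    .oe_stop("statistics error: need >= 2 replicates per group")
  x <- unlist(groups, use.names = FALSE)
  if (log2_transform) x <- log2(x + pseudocount)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  .oneway_f_rows(matrix(x, nrow = 1), g)[1]
}

#' Classify a contrast as up, down or unchanged
#'
#' Upregulated means log2 fold change at or above the threshold;
#' downregulated means strictly below the negated threshold (the asymmetry
#' is deliberate); both require the FDR q-value at or below the cutoff.
#'
#' @param log2fc log2 fold change(s).
#' @param fdr_q BH-adjusted q-value(s).
#' @param lfc_threshold fold-change threshold (log2 units).
#' @param fdr_cutoff FDR cutoff.
#' @return Character vector in `c("up", "down", "unchanged")`.
#' @export
call_de <- function(log2fc, fdr_q, lfc_threshold = 1.0, fdr_cutoff = 0.10) {
  sig <- !is.na(fdr_q) & fdr_q <= fdr_cutoff
  out <- rep("unchanged", length(log2fc))
  out[sig & !is.na(log2fc) & log2fc >= lfc_threshold] <- "up"
  out[sig & !is.na(log2fc) & log2fc < -lfc_threshold] <- "down"
  out
}

#' Differential expression of every cell type against the reference
#'
#' Converts counts to RPKM if needed, runs the per-gene one-way ANOVA
#' across all cell types on `log2(RPKM + pseudocount)`, BH-adjusts the
#' p-values, and calls each non-reference cell type against the reference
#' with [call_de()].  Expressed flags combine the mean-RPKM cutoff with the
#' gene-level FDR.
#'
#' @param x an [expression_matrix()].
#' @param exonic_lengths exon-union lengths (named vector or
#'   `gene_annotation`); required when `x` holds counts.
#' @param pseudocount RPKM pseudocount for log transform and fold changes.
#' @param rpkm_cutoff expressed-call RPKM cutoff (inclusive).
#' @param fdr_cutoff FDR cutoff for DE and expressed calls (inclusive).
#' @param lfc_threshold log2-fold-change threshold for DE calls.
#' @return A `de_profile`: list with `mean_rpkm` (genes x cell types),
#'   `expressed` (logical, same shape), `p_value`, `fdr_q` (per gene), and
#'   `contrasts` (long data frame: `gene_id`, `contrast`, `mean_ref`,
#'   `mean_alt`, `log2fc`, `p_value`, `fdr_q`, `call`, `expressed_alt`,
#'   `expressed_ref`).
#' @export
run_de <- function(x, exonic_lengths = NULL, pseudocount = 0.01,
                   rpkm_cutoff = 0.10, fdr_cutoff = 0.10,
                   lfc_threshold = 1.0) {
  if (!inherits(x, "expression_matrix"))
    .oe_stop("'x' must be an expression_matrix")
  if (x$value_kind == "counts") {
    if (is.null(exonic_lengths))
      .oe_stop("exonic_lengths are required to normalize counts to RPKM")
    x <- to_rpkm(x, exonic_lengths)
  }
  groups <- factor(x$column_cell_type, levels = x$cell_types)
  if (any(table(groups) < 2))
    .oe_stop("statistics error: need >= 2 replicates per cell type")
  rp <- x$values
  logm <- log2(rp + pseudocount)
  p <- .oneway_f_rows(logm, groups)
  q <- benjamini_hochberg(p)

  mean_rpkm <- vapply(x$cell_types, function(ct)
    rowMeans(rp[, groups == ct, drop = FALSE]), numeric(nrow(rp)))
  if (nrow(rp) == 1)
    mean_rpkm <- matrix(mean_rpkm, nrow = 1,
                        dimnames = list(x$gene_ids, x$cell_types))
  expressed <- mean_rpkm >= rpkm_cutoff & q <= fdr_cutoff

  ref <- x$reference
  alts <- setdiff(x$cell_types, ref)
  contrasts <- do.call(rbind, lapply(alts, function(ct) {
    lfc <- log2_fold_change(mean_rpkm[, ct], mean_rpkm[, ref], pseudocount)
    data.frame(
      gene_id = x$gene_ids,
      contrast = ct,
      mean_ref = mean_rpkm[, ref],
      mean_alt = mean_rpkm[, ct],
      log2fc = lfc,
      p_value = p,
      fdr_q = q,
      call = call_de(lfc, q, lfc_threshold, fdr_cutoff),
      expressed_alt = expressed[, ct],
      expressed_ref = expressed[, ref],
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(species = x$species, gene_ids = x$gene_ids,
                 cell_types = x$cell_types, reference = ref,
                 mean_rpkm = mean_rpkm, expressed = expressed,
                 p_value = stats::setNames(p, x$gene_ids),
                 fdr_q = stats::setNames(q, x$gene_ids),
                 contrasts = contrasts,
                 params = list(pseudocount = pseudocount,
                               rpkm_cutoff = rpkm_cutoff,
                               fdr_cutoff = fdr_cutoff,
                               lfc_threshold = lfc_threshold)),
            class = "de_profile")
}

#' @export
print.de_profile <- function(x, ...) {
  cat(sprintf("de_profile: %s, %d genes, reference %s, contrasts: %s\n",
              x$species, length(x$gene_ids), x$reference,
              paste(setdiff(x$cell_types, x$reference), collapse = ", ")))
  invisible(x)
}

#' Call expressed genes in one cell type
#'
#' A gene is expressed when its mean replicate RPKM in the cell type is at
#' or above the cutoff and (optionally) its gene-level FDR q-value is at or
#' below the FDR cutoff; both bounds are inclusive.
#'
#' @param profile a `de_profile` from [run_de()].
#' @param cell_type the cell type to call.
#' @param rpkm_cutoff inclusive RPKM cutoff.
#' @param fdr_cutoff inclusive FDR cutoff.
#' @param use_fdr apply the FDR clause (`TRUE`, the default) or call on
#'   RPKM alone.
#' @return Named logical vector over genes.
#' @export
call_expressed <- function(profile, cell_type, rpkm_cutoff = 0.10,
                           fdr_cutoff = 0.10, use_fdr = TRUE) {
  if (!inherits(profile, "de_profile"))
    .oe_stop("'profile' must be a de_profile")
  if (!cell_type %in% profile$cell_types)
    .oe_stop("lookup error: unknown cell type '%s'", cell_type)
  ok <- profile$mean_rpkm[, cell_type] >= rpkm_cutoff
  if (use_fdr) ok <- ok & profile$fdr_q <= fdr_cutoff
  stats::setNames(ok, profile$gene_ids)
}
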