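#' Read a gene annotation from GTF/GFF
#'
#' Imports gene, transcript and exon features and summarizes one record
#' per gene: coordinates, strand, transcript count, and the exonic length
#' (the length of the union of all exon intervals across transcripts).
#' Genes with no exon features are skipped with a warning.
#'
#' @param path GTF/GFF file.
#' @return A `gene_annotation` data frame ordered by
#'   `(chromosome, start, gene_id)` with columns `gene_id`, `gene_name`,
#'   `chromosome`, `start`, `end`, `strand`, `transcript_count`,
#'   `exonic_length`; exon intervals are kept in `attr(, "exons")`.
#' @export
read_gtf <- function(path) {
  content <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(content)) | startsWith(trimws(content), "#")
  gr <- if (all(blank)) GenomicRanges::GRanges() else
    tryCatch(rtracklayer::import(path),
             error = function(e)
               .oe_stop("parse error in '%s': %s", path,
                        conditionMessage(e)))
  empty <- function() {
    ann <- data.frame(gene_id = character(), gene_name = character(),
                      chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      transcript_count = integer(),
                      exonic_length = numeric(), stringsAsFactors = FALSE)
    attr(ann, "exons") <- data.frame(gene_id = character(),
                                     exon_number = integer(),
                                     start = integer(), end = integer(),
                                     stringsAsFactors = FALSE)
    class(ann) <- c("gene_annotation", "data.frame")
    ann
  }
  if (length(gr) == 0) {
    warning(sprintf("empty annotation file '%s'", path))
    return(empty())
  }
  type <- as.character(gr$type)
  exons <- gr[type == "exon"]
  if (length(exons) == 0) {
    warning(sprintf("no exon features in '%s'; all genes skipped", path))
    return(empty())
  }
  exon_ids <- as.character(exons$gene_id)
  by_gene <- GenomicRanges::split(GenomicRanges::granges(exons), exon_ids)
  red <- GenomicRanges::reduce(by_gene)
  exonic_length <- sum(GenomicRanges::width(red))

  genes <- gr[type == "gene"]
  gene_ids <- if (length(genes) > 0) as.character(genes$gene_id) else
    unique(exon_ids)
  no_exons <- setdiff(gene_ids, exon_ids)
  if (length(no_exons) > 0) {
    warning(sprintf("skipping %d gene(s) with no exons: %s",
                    length(no_exons),
                    paste(utils::head(no_exons, 5), collapse = ", ")))
    gene_ids <- setdiff(gene_ids, no_exons)
  }
  # gene coordinates: from gene rows when present, else exon spans
  span <- range(by_gene)
  if (length(genes) > 0) {
    gi <- match(gene_ids, as.character(genes$gene_id))
    chrom <- as.character(GenomicRanges::seqnames(genes))[gi]
    start <- GenomicRanges::start(genes)[gi]
    end <- GenomicRanges::end(genes)[gi]
    strand <- as.character(GenomicRanges::strand(genes))[gi]
    gname <- if (!is.null(genes$gene_name))
      as.character(genes$gene_name)[gi] else rep(NA_character_, length(gi))
  } else {
    si <- match(gene_ids, names(span))
    chrom <- vapply(span[si], function(r)
      as.character(GenomicRanges::seqnames(r))[1], character(1))
    start <- vapply(span[si], function(r)
      min(GenomicRanges::start(r)), numeric(1))
    end <- vapply(span[si], function(r)
      max(GenomicRanges::end(r)), numeric(1))
    strand <- rep("+", length(gene_ids))
    gname <- rep(NA_character_, length(gene_ids))
  }
  gname[is.na(gname)] <- gene_ids[is.na(gname)]

  tx <- gr[type == "transcript"]
  transcript_count <- if (length(tx) > 0) {
    tc <- tapply(as.character(tx$transcript_id), as.character(tx$gene_id),
                 function(v) length(unique(v)))
    unname(ifelse(is.na(tc[gene_ids]), 1L, tc[gene_ids]))
  } else {
    tc <- tapply(as.character(exons$transcript_id), exon_ids,
                 function(v) length(unique(v)))
    unname(ifelse(is.na(tc[gene_ids]), 1L, tc[gene_ids]))
  }

  ann <- data.frame(
    gene_id = gene_ids,
    gene_name = gname,
    chromosome = chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    transcript_count = as.integer(transcript_count),
    exonic_length = as.numeric(exonic_length[gene_ids]),
    stringsAsFactors = FALSE
  )
  ann <- ann[order(ann$chromosome, ann$start, ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  exdf <- data.frame(
    gene_id = exon_ids,
    exon_number = stats::ave(seq_along(exon_ids), exon_ids, FUN = seq_along),
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons),
    stringsAsFactors = FALSE
  )
  attr(ann, "exons") <- exdf
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write a gene annotation as GTF
#'
#' Emits gene, transcript and exon features; genes with
#' `transcript_count > 1` get that many transcript variants sharing the
#' gene's exons.
#'
#' @param annotation a `gene_annotation` (with exon intervals in
#'   `attr(, "exons")`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  exons <- attr(annotation, "exons")
  con <- file(path, "w")
  on.exit(close(con))
  attrs <- function(...) {
    kv <- list(...)
    paste(vapply(names(kv), function(k)
      sprintf('%s "%s";', k, kv[[k]]), character(1)), collapse = " ")
  }
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    writeLines(paste(g$chromosome, "sim", "gene", g$start, g$end, ".",
                     g$strand, ".",
                     attrs(gene_id = g$gene_id, gene_name = g$gene_name),
                     sep = "\t"), con)
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (tnum in seq_len(g$transcript_count)) {
      tid <- sprintf("%s.t%d", g$gene_id, tnum)
      writeLines(paste(g$chromosome, "sim", "transcript", g$start, g$end,
                       ".", g$strand, ".",
                       attrs(gene_id = g$gene_id, transcript_id = tid,
                             gene_name = g$gene_name),
                       sep = "\t"), con)
      for (j in seq_len(nrow(ex))) {
        writeLines(paste(g$chromosome, "sim", "exon", ex$start[j],
                         ex$end[j], ".", g$strand, ".",
                         attrs(gene_id = g$gene_id, transcript_id = tid,
                               gene_name = g$gene_name,
                               exon_number = ex$exon_number[j]),
                         sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' Header: `gene_id` plus one `cell_type:replicate` column per library;
#' for count matrices the per-column library sizes go to a companion TSV.
#'
#' @param x an [expression_matrix()].
#' @param path output TSV.
#' @param library_sizes_path companion TSV (`column`, `total_mapped`);
#'   required for counts.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, library_sizes_path = NULL) {
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (x$value_kind == "counts") {
    if (is.null(library_sizes_path))
      .oe_stop("library_sizes_path is required for count matrices")
    utils::write.table(
      data.frame(column = names(x$library_sizes),
                 total_mapped = unname(x$library_sizes)),
      library_sizes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with `gene_id` plus `cell_type:replicate` columns.
#' @param species species tag.
#' @param reference reference cell type.
#' @param value_kind `"counts"` or `"rpkm"`.
#' @param library_sizes named vector, or path to the companion TSV written
#'   by [write_expression_tsv()]; required for counts.
#' @param cell_types optional explicit cell-type order.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, species, reference,
                                value_kind = c("counts", "rpkm"),
                                library_sizes = NULL, cell_types = NULL) {
  value_kind <- match.arg(value_kind)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    .oe_stop("format error: expression file is missing required column 'gene_id'")
  vals <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(vals) <- df$gene_id
  if (is.character(library_sizes) && length(library_sizes) == 1 &&
      file.exists(library_sizes)) {
    ls_df <- utils::read.delim(library_sizes, stringsAsFactors = FALSE)
    library_sizes <- stats::setNames(ls_df$total_mapped, ls_df$column)
  }
  expression_matrix(vals, species = species, cell_types = cell_types,
                    reference = reference, value_kind = value_kind,
                    library_sizes = library_sizes)
}

# Biomart-dialect homology TSV writer used by the simulator; `label` is
# the query species display label (capitalized), e.g. "Mouse"
.write_homology_biomart <- function(pairs, path, label,
                                    transcript_counts = NULL) {
  cap <- paste0(toupper(substr(label, 1, 1)), substr(label, 2, nchar(label)))
  df <- data.frame(
    a = pairs$ref_gene_id, b = pairs$ref_gene_name,
    c = pairs$query_gene_id, d = pairs$query_gene_name,
    e = pairs$homology_type, f = pairs$percent_identity,
    g = pairs$goc_score, h = pairs$wga_score,
    stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("Gene stable ID", "Gene name",
                 paste(cap, "gene stable ID"), paste(cap, "gene name"),
                 paste(cap, "homology type"),
                 sprintf("%%id. target %s gene identical to query gene", cap),
                 paste(cap, "Gene-order conservation score"),
                 paste(cap, "Whole-genome alignment coverage"))
  if (!is.null(transcript_counts)) {
    reps <- transcript_counts[pairs$ref_gene_id]
    reps[is.na(reps)] <- 1L
    df <- df[rep(seq_len(nrow(df)), times = reps), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a complete simulated study to disk
#'
#' Writes both annotations (GTF), the Biomart-dialect homology TSV (one
#' row per reference transcript when the configuration enables
#' multi-transcript genes), the expression TSVs with library sizes, the
#' planted-truth TSVs and the configuration YAML.
#'
#' @param sim result of [simulate_genomes()].
#' @param expr result of [simulate_expression()].
#' @param dir output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_simulation <- function(sim, expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$truth$config
  paths <- list(
    annotation_a = file.path(dir, "annotation_a.gtf"),
    annotation_b = file.path(dir, "annotation_b.gtf"),
    homology = file.path(dir, "homology.tsv"),
    expression_a = file.path(dir, "expression_a.tsv"),
    expression_b = file.path(dir, "expression_b.tsv"),
    library_sizes_a = file.path(dir, "library_sizes_a.tsv"),
    library_sizes_b = file.path(dir, "library_sizes_b.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_genes_a = file.path(dir, "truth_genes_a.tsv"),
    truth_genes_b = file.path(dir, "truth_genes_b.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_gtf(sim$annotation_a, paths$annotation_a)
  write_gtf(sim$annotation_b, paths$annotation_b)
  tc <- if (cfg$multi_transcript)
    stats::setNames(sim$annotation_a$transcript_count,
                    sim$annotation_a$gene_id)
  .write_homology_biomart(sim$homology, paths$homology, cfg$species_b,
                          transcript_counts = tc)
  write_expression_tsv(expr$matrix_a, paths$expression_a,
                       paths$library_sizes_a)
  write_expression_tsv(expr$matrix_b, paths$expression_b,
                       paths$library_sizes_b)
  wt <- function(df, p) utils::write.table(df, p, sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(sim$truth$pairs, paths$truth_pairs)
  wt(sim$truth$genes_a, paths$truth_genes_a)
  wt(sim$truth$genes_b, paths$truth_genes_b)
  yaml::write_yaml(unclass(cfg), paths$config)
  invisible(paths)
}
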