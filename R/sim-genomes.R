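#' Simulate a pair of annotated genomes with a planted homology graph
#'
#' Builds species A and B gene annotations from a shared set of base genes.
#' Conserved base genes occupy syntenic neighborhoods in both species
#' (duplicated copies are placed in tandem); a configured fraction of
#' species-B genes is relocated to random positions to degrade gene-order
#' conservation; orphan genes are present in one species only and carry no
#' homology edge.  Per-pair percent identity and WGA coverage are drawn
#' from the configured distributions.  All planted labels are recorded in a
#' `comparison_truth` object.
#'
#' @param config a [sim_config()].
#' @return A list with elements `annotation_a`, `annotation_b` (class
#'   `gene_annotation`, see [read_gtf()] for the column contract),
#'   `homology` (a raw homology pair data frame in canonical columns, GOC
#'   unset), and `truth` (class `comparison_truth`: `$pairs` with the true
#'   homology class and drawn scores, `$genes_a`/`$genes_b` with planted DE
#'   labels, unique-expression cell types, TF flags and rearrangement
#'   flags).
#' @export
simulate_genomes <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_base_genes
    u <- stats::runif(n)
    category <- ifelse(u < config$orphan_prob_a, "orphan_a",
                ifelse(u < config$orphan_prob_a + config$orphan_prob_b,
                       "orphan_b", "conserved"))
    conserved <- which(category == "conserved")
    copies_a <- ifelse(category == "orphan_b", 0L, 1L)
    copies_b <- ifelse(category == "orphan_a", 0L, 1L)
    copies_a[conserved] <- 1L +
      stats::rbinom(length(conserved), 1, config$paralog_expansion_prob)
    copies_b[conserved] <- 1L +
      stats::rbinom(length(conserved), 1, config$paralog_expansion_prob_b)

    base_name <- sprintf("fam%04d", seq_len(n))

    genes_side <- function(copies, id_prefix, name_fun) {
      base_id <- rep(seq_len(n), times = copies)
      copy <- unlist(lapply(copies, seq_len), use.names = FALSE)
      data.frame(
        base_id = base_id,
        copy = copy,
        gene_id = sprintf("%s%04d%s", id_prefix, base_id,
                          ifelse(copy > 1, paste0("-", copy), "")),
        gene_name = name_fun(base_name[base_id], copy),
        stringsAsFactors = FALSE
      )
    }
    # zebrafish-style lowercase names with paralog letters; mouse-style
    # capitalized names
    genes_a <- genes_side(copies_a, "GA", function(nm, copy)
      paste0(nm, ifelse(copy > 1, letters[copy], "")))
    genes_b <- genes_side(copies_b, "GB", function(nm, copy) {
      nm <- paste0(toupper(substr(nm, 1, 1)), substr(nm, 2, nchar(nm)))
      paste0(nm, ifelse(copy > 1, letters[copy], ""))
    })

    # species B gene order: base order, then random relocation of a fraction
    nb <- nrow(genes_b)
    n_move <- round(config$rearrangement_rate * nb)
    moved <- sort(sample.int(nb, n_move))
    key <- rep(NA_real_, nb)
    kept <- setdiff(seq_len(nb), moved)
    key[kept] <- seq_along(kept)
    key[moved] <- stats::runif(n_move, 0, length(kept) + 1)
    order_b <- order(key, seq_len(nb))
    genes_b$rearranged <- seq_len(nb) %in% moved
    genes_b <- genes_b[order_b, , drop = FALSE]
    genes_a$rearranged <- FALSE

    annotation_a <- .sim_build_annotation(genes_a, config$n_chromosomes_a,
                                          config$multi_transcript, "a")
    annotation_b <- .sim_build_annotation(genes_b, config$n_chromosomes_b,
                                          config$multi_transcript, "b")

    # homology edges: complete bipartite block per conserved base gene
    edges <- lapply(conserved, function(i) {
      ga <- genes_a[genes_a$base_id == i, c("gene_id", "gene_name")]
      gb <- genes_b[genes_b$base_id == i, c("gene_id", "gene_name")]
      cls <- if (nrow(ga) == 1 && nrow(gb) == 1) "one2one"
             else if (nrow(ga) > 1 && nrow(gb) > 1) "many2many"
             else "many2one"
      grid <- expand.grid(ai = seq_len(nrow(ga)), bi = seq_len(nrow(gb)))
      data.frame(
        base_id = i,
        ref_gene_id = ga$gene_id[grid$ai],
        ref_gene_name = ga$gene_name[grid$ai],
        query_gene_id = gb$gene_id[grid$bi],
        query_gene_name = gb$gene_name[grid$bi],
        homology_type = cls,
        stringsAsFactors = FALSE
      )
    })
    pairs <- do.call(rbind, edges)
    if (is.null(pairs)) {
      pairs <- data.frame(base_id = integer(), ref_gene_id = character(),
                          ref_gene_name = character(),
                          query_gene_id = character(),
                          query_gene_name = character(),
                          homology_type = character(),
                          stringsAsFactors = FALSE)
    }
    np <- nrow(pairs)
    clip01 <- function(x) pmin(100, pmax(0, x))
    pairs$percent_identity <- round(clip01(stats::rnorm(
      np, config$pid_distribution$mean, config$pid_distribution$sd)), 2)
    wga <- round(clip01(stats::rnorm(
      np, config$wga_distribution$mean, config$wga_distribution$sd)), 2)
    miss <- stats::runif(np) < (config$wga_distribution$missing_prob %||% 0)
    wga[miss] <- NA_real_
    pairs$wga_score <- wga
    pairs$goc_score <- NA_real_  # induced by placement; computed downstream

    # planted expression structure on conserved base genes
    all_ct <- c(config$cell_types_a, config$cell_types_b)
    n_cons <- length(conserved)
    uniq_bases <- sample(conserved,
                         round(config$unique_expression_fraction * n_cons))
    rest <- setdiff(conserved, uniq_bases)
    de_bases <- sample(rest, min(length(rest),
                                 round(config$de_fraction * n_cons)))
    tf_bases <- sample(conserved, round(config$tf_fraction * n_cons))

    de_label <- rep("null", n)
    de_label[de_bases] <- sample(c("up", "down"), length(de_bases),
                                 replace = TRUE)
    unique_ct <- rep(NA_character_, n)
    unique_ct[uniq_bases] <- sample(all_ct, length(uniq_bases),
                                    replace = TRUE)
    tf <- seq_len(n) %in% tf_bases

    decorate <- function(g) {
      g$de_label <- de_label[g$base_id]
      g$unique_cell_type <- unique_ct[g$base_id]
      g$tf <- tf[g$base_id]
      g
    }
    truth <- list(
      pairs = pairs,
      genes_a = decorate(genes_a),
      genes_b = decorate(genes_b),
      config = config
    )
    class(truth) <- "comparison_truth"

    homology <- pairs[, c("ref_gene_id", "ref_gene_name", "query_gene_id",
                          "query_gene_name", "homology_type",
                          "percent_identity", "goc_score", "wga_score")]
    rownames(homology) <- NULL

    list(annotation_a = annotation_a, annotation_b = annotation_b,
         homology = homology, truth = truth)
  })
}

# lay ordered genes onto chromosomes with simulated exon structure;
# `genes` rows are already in final genomic order
.sim_build_annotation <- function(genes, n_chrom, multi_transcript, tag) {
  ng <- nrow(genes)
  chrom_idx <- if (ng == 0) integer() else
    as.integer(cut(seq_len(ng), breaks = n_chrom, labels = FALSE))
  n_exons <- sample(1:4, ng, replace = TRUE)
  transcript_count <- if (multi_transcript)
    sample(1:3, ng, replace = TRUE) else rep(1L, ng)
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  exon_lens <- lapply(n_exons, function(k)
    pmax(50L, as.integer(round(stats::rlnorm(k, log(300), 0.6)))))
  intron_lens <- lapply(n_exons, function(k)
    if (k > 1) as.integer(round(stats::runif(k - 1, 200, 2000))) else integer())
  span <- vapply(seq_len(ng), function(i)
    sum(exon_lens[[i]]) + sum(intron_lens[[i]]), numeric(1))

  start <- integer(ng)
  pos <- stats::setNames(rep(1L, n_chrom), seq_len(n_chrom))
  exon_rows <- vector("list", ng)
  for (i in seq_len(ng)) {
    ch <- chrom_idx[i]
    start[i] <- pos[[ch]]
    pos[[ch]] <- pos[[ch]] + as.integer(span[i]) + 1000L
    es <- start[i] + cumsum(c(0L, utils::head(exon_lens[[i]], -1) +
                                 intron_lens[[i]]))
    exon_rows[[i]] <- data.frame(
      gene_id = genes$gene_id[i],
      exon_number = seq_along(es),
      start = es,
      end = es + exon_lens[[i]] - 1L,
      stringsAsFactors = FALSE
    )
  }
  ann <- data.frame(
    gene_id = genes$gene_id,
    gene_name = genes$gene_name,
    chromosome = paste0("chr", tag, chrom_idx),
    start = start,
    end = start + as.integer(span) - 1L,
    strand = strand,
    transcript_count = transcript_count,
    exonic_length = vapply(exon_lens, sum, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(ann) <- NULL
  attr(ann, "exons") <- do.call(rbind, exon_rows) %||%
    data.frame(gene_id = character(), exon_number = integer(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
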