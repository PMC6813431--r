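#' Simulate replicate expression matrices with planted structure
#'
#' Draws a per-gene baseline RPKM from the configured log-normal, applies
#' the planted differential-expression shifts (non-reference cell types
#' shifted by the configured log2 effect) and unique-expression zeroing,
#' then samples negative-binomial read counts per replicate column around
#' length- and depth-scaled means.  Counts convert to RPKM through the
#' annotation's exonic lengths via [to_rpkm()].
#'
#' @param config the [sim_config()] used for [simulate_genomes()].
#' @param annotation_a,annotation_b the annotations returned by
#'   [simulate_genomes()].
#' @param truth the `comparison_truth` returned by [simulate_genomes()].
#' @return A list with `matrix_a` and `matrix_b`, each an
#'   [expression_matrix()] of counts with per-column library sizes.
#' @export
simulate_expression <- function(config, annotation_a, annotation_b, truth) {
  config <- validate_sim_config(config)
  if (!inherits(truth, "comparison_truth"))
    .oe_stop("structural error: 'truth' is not a comparison_truth object")
  tcfg <- truth$config
  if (!identical(tcfg$cell_types_a, config$cell_types_a) ||
      !identical(tcfg$cell_types_b, config$cell_types_b))
    .oe_stop("structural error: cell-type lists in config do not match the truth object")
  if (!setequal(truth$genes_a$gene_id, annotation_a$gene_id) ||
      !setequal(truth$genes_b$gene_id, annotation_b$gene_id))
    .oe_stop("structural error: annotations do not match the truth object")

  # independent stream from the genome draw, still fully seed-determined
  withr::with_seed(config$seed + 1L, {
    matrix_a <- .sim_expr_one(truth$genes_a, annotation_a,
                              config$cell_types_a, config$reference_a,
                              config$species_a, config)
    matrix_b <- .sim_expr_one(truth$genes_b, annotation_b,
                              config$cell_types_b, config$reference_b,
                              config$species_b, config)
    list(matrix_a = matrix_a, matrix_b = matrix_b)
  })
}

.sim_expr_one <- function(genes, annotation, cell_types, reference,
                          species, config) {
  idx <- match(annotation$gene_id, genes$gene_id)
  genes <- genes[idx, , drop = FALSE]
  ng <- nrow(genes)
  mu_sig <- config$expression_lognormal_mu_sigma
  baseline <- exp(stats::rnorm(ng, mu_sig[1], mu_sig[2]))

  mean_rpkm <- matrix(baseline, nrow = ng, ncol = length(cell_types),
                      dimnames = list(annotation$gene_id, cell_types))
  mult <- 2^config$log2fc_effect
  for (ct in setdiff(cell_types, reference)) {
    mean_rpkm[genes$de_label == "up", ct] <-
      mean_rpkm[genes$de_label == "up", ct] * mult
    mean_rpkm[genes$de_label == "down", ct] <-
      mean_rpkm[genes$de_label == "down", ct] / mult
  }
  is_unique <- !is.na(genes$unique_cell_type)
  mean_rpkm[is_unique, ] <- 0
  for (ct in cell_types) {
    sel <- is_unique & genes$unique_cell_type == ct
    mean_rpkm[sel, ct] <- baseline[sel]
  }

  len_kb <- annotation$exonic_length / 1e3
  cols <- as.vector(t(outer(cell_types, seq_len(config$n_replicates),
                            paste, sep = ":")))
  lib <- round(stats::rnorm(length(cols), config$library_size,
                            0.05 * config$library_size))
  lib <- pmax(lib, 1)
  names(lib) <- cols
  values <- matrix(0, nrow = ng, ncol = length(cols),
                   dimnames = list(annotation$gene_id, cols))
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  for (j in seq_along(cols)) {
    ct <- sub(":.*$", "", cols[j])
    mu <- mean_rpkm[, ct] * len_kb * lib[j] / 1e6
    values[, j] <- if (is.finite(size))
      stats::rnbinom(ng, mu = mu, size = size)
    else
      stats::rpois(ng, lambda = mu)
  }
  expression_matrix(values, species = species, cell_types = cell_types,
                    reference = reference, value_kind = "counts",
                    library_sizes = lib)
}
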