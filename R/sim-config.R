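#' Configuration for the paired-genome simulator
#'
#' Defines the study conditions the simulator emulates: two annotated
#' genomes related by a homology graph with one-to-one, many-to-one and
#' many-to-many structure, plus replicate expression matrices for the six
#' inner-ear cell types with planted differential expression, planted
#' uniquely-expressed genes and planted transcription-factor labels.
#'
#' @param n_base_genes number of ancestral ("base") genes the two genomes
#'   are built from.
#' @param n_chromosomes_a,n_chromosomes_b chromosome counts per species.
#' @param paralog_expansion_prob probability that a conserved base gene is
#'   duplicated in species A (models the zebrafish genome duplication; the
#'   duplicate is placed in tandem and creates a many-to-one edge).
#' @param paralog_expansion_prob_b probability of the analogous duplication
#'   in species B; when both fire the base gene yields a many-to-many
#'   component.
#' @param orphan_prob_a,orphan_prob_b probabilities that a base gene is
#'   species-unique (present in one annotation, absent from the homology
#'   graph).
#' @param rearrangement_rate fraction of species-B genes relocated to a
#'   random genomic position, degrading gene-order conservation.
#' @param pid_distribution list with `mean` and `sd`: per-pair percent
#'   identity is drawn from a normal with these parameters, clipped to
#'   \[0, 100\].
#' @param wga_distribution list with `mean`, `sd` and `missing_prob`:
#'   per-pair whole-genome-alignment coverage score, clipped to \[0, 100\],
#'   set missing with probability `missing_prob`.
#' @param cell_types_a,cell_types_b ordered cell-type names per species.
#' @param reference_a,reference_b the reference (hair-cell) type per
#'   species; must appear in the corresponding cell-type list.
#' @param species_a,species_b species labels used in output file dialects.
#' @param n_replicates biological replicates per cell type (>= 2).
#' @param de_fraction fraction of conserved base genes planted as
#'   differentially expressed (up or down, equal odds) in all non-reference
#'   cell types of both species.
#' @param unique_expression_fraction fraction of conserved base genes
#'   expressed in exactly one of the combined cell types and silent
#'   everywhere else (in both species).
#' @param tf_fraction fraction of conserved base genes flagged as
#'   transcription factors in the planted truth.
#' @param log2fc_effect planted effect magnitude (log2 units) for
#'   differentially expressed genes.
#' @param expression_lognormal_mu_sigma length-2 numeric: mean and sd of
#'   the per-gene baseline RPKM on the natural-log scale.
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (`size = 1/nb_dispersion`); `0` gives Poisson counts.
#' @param library_size mean total mapped reads per sequencing library.
#' @param multi_transcript when `TRUE`, genes carry 1--3 transcript
#'   variants and the homology export is written with one row per
#'   reference-gene transcript (the Biomart redundancy that
#'   [deduplicate_transcript_rows()] removes).
#' @param seed integer seed; identical configurations (including the seed)
#'   produce identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_genomes()], [simulate_expression()]
#' @export
sim_config <- function(n_base_genes = 1200,
                       n_chromosomes_a = 3,
                       n_chromosomes_b = 3,
                       paralog_expansion_prob = 0.12,
                       paralog_expansion_prob_b = 0.02,
                       orphan_prob_a = 0.05,
                       orphan_prob_b = 0.05,
                       rearrangement_rate = 0.08,
                       pid_distribution = list(mean = 65, sd = 15),
                       wga_distribution = list(mean = 70, sd = 18,
                                               missing_prob = 0.05),
                       cell_types_a = c("HC", "nsSC"),
                       reference_a = "HC",
                       cell_types_b = c("IHC", "PC", "DC", "OHC"),
                       reference_b = "IHC",
                       species_a = "zebrafish",
                       species_b = "mouse",
                       n_replicates = 3,
                       de_fraction = 0.15,
                       unique_expression_fraction = 0.03,
                       tf_fraction = 0.08,
                       log2fc_effect = 2,
                       expression_lognormal_mu_sigma = c(1.5, 1.2),
                       nb_dispersion = 0.05,
                       library_size = 2e7,
                       multi_transcript = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_base_genes = n_base_genes,
    n_chromosomes_a = n_chromosomes_a,
    n_chromosomes_b = n_chromosomes_b,
    paralog_expansion_prob = paralog_expansion_prob,
    paralog_expansion_prob_b = paralog_expansion_prob_b,
    orphan_prob_a = orphan_prob_a,
    orphan_prob_b = orphan_prob_b,
    rearrangement_rate = rearrangement_rate,
    pid_distribution = pid_distribution,
    wga_distribution = wga_distribution,
    cell_types_a = cell_types_a,
    reference_a = reference_a,
    cell_types_b = cell_types_b,
    reference_b = reference_b,
    species_a = species_a,
    species_b = species_b,
    n_replicates = n_replicates,
    de_fraction = de_fraction,
    unique_expression_fraction = unique_expression_fraction,
    tf_fraction = tf_fraction,
    log2fc_effect = log2fc_effect,
    expression_lognormal_mu_sigma = expression_lognormal_mu_sigma,
    nb_dispersion = nb_dispersion,
    library_size = library_size,
    multi_transcript = multi_transcript,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulator configuration
#'
#' Checks every field's domain and names the offending field on failure.
#'
#' @param config a `sim_config` (or bare list with the same fields).
#' @return The validated `sim_config`, invisibly usable downstream.
#' @export
validate_sim_config <- function(config) {
  if (!is.list(config)) .oe_stop("invalid config: not a list")
  chk_count <- function(field, min = 1) {
    x <- config[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != round(x)) {
      .oe_stop("invalid config field '%s': must be an integer >= %d",
               field, min)
    }
  }
  chk_prob <- function(field) {
    x <- config[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      .oe_stop("invalid config field '%s': must be a probability in [0, 1]",
               field)
  }
  chk_count("n_base_genes")
  chk_count("n_chromosomes_a")
  chk_count("n_chromosomes_b")
  chk_count("n_replicates", min = 2)
  for (f in c("paralog_expansion_prob", "paralog_expansion_prob_b",
              "orphan_prob_a", "orphan_prob_b", "rearrangement_rate",
              "de_fraction", "unique_expression_fraction", "tf_fraction"))
    chk_prob(f)
  for (f in c("pid_distribution", "wga_distribution")) {
    d <- config[[f]]
    if (!is.list(d) || !is.numeric(d$mean) || !is.numeric(d$sd) || d$sd < 0)
      .oe_stop("invalid config field '%s': needs numeric mean and sd >= 0", f)
  }
  mp <- config$wga_distribution$missing_prob %||% 0
  if (!is.numeric(mp) || mp < 0 || mp > 1)
    .oe_stop("invalid config field 'wga_distribution': missing_prob must be in [0, 1]")
  for (side in c("a", "b")) {
    cts <- config[[paste0("cell_types_", side)]]
    ref <- config[[paste0("reference_", side)]]
    if (!is.character(cts) || length(cts) < 2 || anyDuplicated(cts))
      .oe_stop("invalid config field 'cell_types_%s': need >= 2 distinct cell types",
               side)
    if (!is.character(ref) || length(ref) != 1 || !(ref %in% cts))
      .oe_stop("invalid config field 'reference_%s': must name one of cell_types_%s",
               side, side)
  }
  if (length(intersect(config$cell_types_a, config$cell_types_b)) > 0)
    .oe_stop("invalid config field 'cell_types_b': cell-type names must differ between species")
  es <- config$expression_lognormal_mu_sigma
  if (!is.numeric(es) || length(es) != 2 || es[2] < 0)
    .oe_stop("invalid config field 'expression_lognormal_mu_sigma': need c(mu, sigma >= 0)")
  if (!is.numeric(config$log2fc_effect) || length(config$log2fc_effect) != 1)
    .oe_stop("invalid config field 'log2fc_effect': must be a single number")
  if (!is.numeric(config$nb_dispersion) || config$nb_dispersion < 0)
    .oe_stop("invalid config field 'nb_dispersion': must be >= 0")
  if (!is.numeric(config$library_size) || config$library_size <= 0)
    .oe_stop("invalid config field 'library_size': must be > 0")
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      is.na(config$seed) || abs(config$seed) >= 2^31 - 2)
    .oe_stop("invalid config field 'seed': must be a 32-bit integer")
  config$seed <- as.integer(config$seed)
  class(config) <- "sim_config"
  config
}
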