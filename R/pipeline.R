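#' Load and validate a pipeline configuration
#'
#' @param config YAML file path or a named list.  Required fields:
#'   `annotation_a`, `annotation_b`, `homology`, `expression_a`,
#'   `expression_b`, `library_sizes_a`, `library_sizes_b`, `reference_a`,
#'   `reference_b`, `outdir`.  Optional: `dialect`, `populations`,
#'   `unique_cell_types`, `tf_list`, `deafness_list`, `gmt`, `seed`, and a
#'   `thresholds` list (`rpkm_cutoff`, `fdr`, `lfc`, `pseudocount`,
#'   `pid_min`, `goc_min`, `wga_min`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) .oe_stop("validation error: config must be a list or YAML path")
  required <- c("annotation_a", "annotation_b", "homology", "expression_a",
                "expression_b", "library_sizes_a", "library_sizes_b",
                "reference_a", "reference_b", "outdir")
  for (f in required)
    if (is.null(config[[f]]))
      .oe_stop("validation error: config is missing required field '%s'", f)
  for (f in c("annotation_a", "annotation_b", "homology", "expression_a",
              "expression_b", "library_sizes_a", "library_sizes_b",
              "tf_list", "deafness_list", "gmt"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      .oe_stop("validation error: config field '%s' points to a missing file: %s",
               f, config[[f]])
  th <- config$thresholds %||% list()
  config$thresholds <- list(
    rpkm_cutoff = th$rpkm_cutoff %||% 0.10,
    fdr = th$fdr %||% 0.10,
    lfc = th$lfc %||% 1.0,
    pseudocount = th$pseudocount %||% 0.01,
    pid_min = th$pid_min %||% 50,
    goc_min = th$goc_min %||% 75,
    wga_min = th$wga_min %||% 75
  )
  with(config$thresholds, {
    if (rpkm_cutoff < 0 || fdr < 0 || fdr > 1 || lfc < 0 || pseudocount <= 0)
      .oe_stop("validation error: thresholds outside their documented domains")
  })
  config$dialect <- config$dialect %||% "biomart"
  config$populations <- config$populations %||% c("nsSC", "PC", "DC")
  config$seed <- config$seed %||% 1L
  class(config) <- "pipeline_config"
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .oe_stop("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full cross-species comparison pipeline
#'
#' Executes orthology (table build, classification, GOC, high-confidence
#' flags), per-species differential expression against each reference
#' cell type, the cross-species merge, the shared/unique gene-set
#' analyses, optional annotation overlays and enrichment, and writes all
#' result TSVs plus a provenance manifest.  Outputs are deterministic
#' given identical inputs.
#'
#' @param config a [pipeline_config()] (or path/list accepted by it).
#' @return The result bundle, invisibly: `ortab`, `profile_a`,
#'   `profile_b`, `merged`, `common_up`, `common_down`, `venn_up`,
#'   `venn_down`, `unique_sets`, overlays/enrichment when configured, and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  th <- config$thresholds
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  ann_a <- .stage("read_annotations", read_gtf(config$annotation_a))
  ann_b <- .stage("read_annotations", read_gtf(config$annotation_b))
  raw_pairs <- .stage("read_homology",
                      read_homology(config$homology, config$dialect))
  ortab <- .stage("orthology", build_ortholog_table(
    raw_pairs, ann_a, ann_b, pid_min = th$pid_min, goc_min = th$goc_min,
    wga_min = th$wga_min))

  read_expr <- function(path, ls_path, species, reference) {
    read_expression_tsv(path, species = species, reference = reference,
                        value_kind = "counts", library_sizes = ls_path)
  }
  mat_a <- .stage("read_expression",
                  read_expr(config$expression_a, config$library_sizes_a,
                            "species_a", config$reference_a))
  mat_b <- .stage("read_expression",
                  read_expr(config$expression_b, config$library_sizes_b,
                            "species_b", config$reference_b))
  profile_a <- .stage("differential_expression", run_de(
    mat_a, ann_a, pseudocount = th$pseudocount,
    rpkm_cutoff = th$rpkm_cutoff, fdr_cutoff = th$fdr,
    lfc_threshold = th$lfc))
  profile_b <- .stage("differential_expression", run_de(
    mat_b, ann_b, pseudocount = th$pseudocount,
    rpkm_cutoff = th$rpkm_cutoff, fdr_cutoff = th$fdr,
    lfc_threshold = th$lfc))

  merged <- .stage("merge", merge_expression(ortab, profile_a, profile_b))

  pops <- config$populations
  common_up <- .stage("set_algebra", common_regulated(merged, "up", pops))
  common_down <- .stage("set_algebra",
                        common_regulated(merged, "down", pops))
  single <- function(direction) lapply(pops, function(p)
    common_regulated(merged, direction, p))
  venn_up <- venn_down <- NULL
  if (length(pops) == 3) {
    venn_up <- .stage("set_algebra",
                      do.call(venn3, c(single("up"),
                                       list(set_names = pops))))
    venn_down <- .stage("set_algebra",
                        do.call(venn3, c(single("down"),
                                         list(set_names = pops))))
  }
  unique_sets <- .stage("set_algebra", unique_expression(
    merged, cell_types = config$unique_cell_types,
    rpkm_cutoff = th$rpkm_cutoff))

  bundle <- list(ortab = ortab, profile_a = profile_a,
                 profile_b = profile_b, merged = merged,
                 common_up = common_up, common_down = common_down,
                 common_up_hc = filter_high_confidence(common_up, ortab),
                 common_down_hc = filter_high_confidence(common_down, ortab),
                 venn_up = venn_up, venn_down = venn_down,
                 unique_sets = unique_sets)

  if (!is.null(config$tf_list)) {
    tf <- utils::read.delim(config$tf_list, stringsAsFactors = FALSE)[[1]]
    # match floor off: the common-up subset is expected to contain only a
    # small fraction of the TF list
    bundle$tf_up <- .stage("overlay", overlay_annotation(
      merged[merged$pair_id %in% common_up, , drop = FALSE], tf,
      match_floor = 0))
  }
  if (!is.null(config$deafness_list)) {
    dg <- utils::read.delim(config$deafness_list,
                            stringsAsFactors = FALSE)[[1]]
    bundle$deafness <- .stage("overlay", overlay_annotation(
      merged[merged$analyzed, , drop = FALSE], dg))
  }
  if (!is.null(config$gmt)) {
    gmt <- .stage("enrichment", read_gmt(config$gmt))
    universe <- merged$ref_gene_id[merged$analyzed]
    qry <- merged$ref_gene_id[merged$pair_id %in% common_up]
    bundle$enrichment <- .stage("enrichment", enrich(
      qry, gmt, universe = universe, fdr_cutoff = NULL))
  }

  bundle$manifest <- .stage("write_outputs",
                            .write_pipeline_outputs(bundle, config))
  invisible(bundle)
}

.write_pipeline_outputs <- function(bundle, config) {
  outdir <- config$outdir
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  write_ortholog_table(bundle$ortab, file.path(outdir, "ortholog_table.tsv"),
                       file.path(outdir, "relationship_tallies.tsv"))
  wt(bundle$profile_a$contrasts, "de_a.tsv")
  wt(bundle$profile_b$contrasts, "de_b.tsv")
  wt(as.data.frame(bundle$merged)[order(bundle$merged$pair_id), ],
     "merged_ortholog_expression.tsv")
  set_df <- function(sets) {
    data.frame(set = rep(names(sets), lengths(sets)),
               pair_id = unlist(sets, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  wt(set_df(list(common_up = sort(bundle$common_up),
                 common_down = sort(bundle$common_down),
                 common_up_hc = sort(bundle$common_up_hc),
                 common_down_hc = sort(bundle$common_down_hc))),
     "common_regulated.tsv")
  if (!is.null(bundle$venn_up)) {
    wt(set_df(lapply(bundle$venn_up$regions, sort)), "venn_up.tsv")
    wt(set_df(lapply(bundle$venn_down$regions, sort)), "venn_down.tsv")
  }
  wt(set_df(lapply(bundle$unique_sets, sort)), "unique_expression.tsv")
  if (!is.null(bundle$enrichment)) wt(bundle$enrichment, "enrichment.tsv")
  if (!is.null(bundle$tf_up)) wt(bundle$tf_up, "tf_overlay.tsv")

  cfg_json <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_json)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("orthoexpr")),
    rows = list(
      ortholog_pairs = nrow(bundle$ortab$pairs),
      merged = nrow(bundle$merged),
      excluded_no_data = attr(bundle$merged, "n_excluded"),
      common_up = length(bundle$common_up),
      common_down = length(bundle$common_down),
      common_up_hc = length(bundle$common_up_hc),
      common_down_hc = length(bundle$common_down_hc),
      unique_expression = sum(lengths(bundle$unique_sets))
    )
  )
  unlink(cfg_json)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  manifest
}

#' Compare pipeline results against planted truth
#'
#' Computes recovery metrics for a simulated study: homology-class
#' accuracy, high-confidence flag agreement (truth scores plus
#' placement-induced GOC), per-contrast differential-expression recall and
#' precision against the planted labels, and unique-expression recall.
#'
#' @param bundle result of [run_pipeline()], or a list with `ortab`,
#'   `profile_a`, `profile_b`, `merged`, `unique_sets`.
#' @param truth the `comparison_truth` from [simulate_genomes()].
#' @return Named list of metrics.
#' @export
recovery_report <- function(bundle, truth) {
  tp <- truth$pairs
  tp$pair_id <- paste(tp$ref_gene_id, tp$query_gene_id, sep = "|")
  op <- bundle$ortab$pairs
  idx <- match(tp$pair_id, op$pair_id)
  class_acc <- mean(op$homology_type[idx] == tp$homology_type, na.rm = TRUE)

  expected_hc <- call_high_confidence(tp$percent_identity,
                                      op$goc_score[idx], tp$wga_score)
  hc_acc <- mean(op$high_confidence[idx] == expected_hc, na.rm = TRUE)

  de_metrics <- function(profile, genes) {
    gi <- match(profile$contrasts$gene_id, genes$gene_id)
    truth_label <- genes$de_label[gi]
    call <- profile$contrasts$call
    called <- call %in% c("up", "down")
    planted <- truth_label %in% c("up", "down")
    list(recall = mean(call[planted] == truth_label[planted]),
         precision = if (any(called))
           mean(truth_label[called] == call[called]) else NA_real_)
  }
  de_a <- de_metrics(bundle$profile_a, truth$genes_a)
  de_b <- de_metrics(bundle$profile_b, truth$genes_b)

  uniq_recall <- NA_real_
  if (!is.null(bundle$unique_sets)) {
    merged <- bundle$merged
    ga <- truth$genes_a
    planted <- ga[!is.na(ga$unique_cell_type), c("gene_id",
                                                 "unique_cell_type")]
    planted <- planted[planted$gene_id %in%
                         merged$ref_gene_id[merged$analyzed], , drop = FALSE]
    planted <- planted[planted$unique_cell_type %in%
                         names(bundle$unique_sets), , drop = FALSE]
    if (nrow(planted) > 0) {
      hit <- vapply(seq_len(nrow(planted)), function(i) {
        pid <- merged$pair_id[merged$ref_gene_id == planted$gene_id[i]]
        any(pid %in% bundle$unique_sets[[planted$unique_cell_type[i]]])
      }, logical(1))
      uniq_recall <- mean(hit)
    }
  }
  list(homology_class_accuracy = class_acc,
       high_confidence_accuracy = hc_acc,
       de_recall_a = de_a$recall, de_precision_a = de_a$precision,
       de_recall_b = de_b$recall, de_precision_b = de_b$precision,
       unique_expression_recall = uniq_recall)
}
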