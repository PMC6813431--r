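# shared simulated study for comparison tests
cmp_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      # clear planted signal so recovery properties are sharp
      sim <- small_sim(log2fc_effect = 3, n_replicates = 4,
                       nb_dispersion = 0.02)
      ortab <- build_ortholog_table(sim$homology, sim$annotation_a,
                                    sim$annotation_b)
      pa <- run_de(sim$matrix_a, sim$annotation_a)
      pb <- run_de(sim$matrix_b, sim$annotation_b)
      merged <- merge_expression(ortab, pa, pb)
      memo <<- list(sim = sim, ortab = ortab, pa = pa, pb = pb,
                    merged = merged)
    }
    memo
  }
})

test_that("merging flags and excludes pairs without expression data", {
  fx <- cmp_fixture()
  # drop 2 query genes from the expression profile
  pb2 <- fx$pb
  drop <- fx$ortab$pairs$query_gene_id[1:2]
  keep <- !(pb2$gene_ids %in% drop)
  pb2$gene_ids <- pb2$gene_ids[keep]
  pb2$mean_rpkm <- pb2$mean_rpkm[keep, , drop = FALSE]
  pb2$expressed <- pb2$expressed[keep, , drop = FALSE]
  pb2$fdr_q <- pb2$fdr_q[keep]
  pb2$p_value <- pb2$p_value[keep]
  pb2$contrasts <- pb2$contrasts[pb2$contrasts$gene_id %in% pb2$gene_ids, ]
  m2 <- merge_expression(fx$ortab, fx$pa, pb2)
  n_drop <- sum(fx$ortab$pairs$query_gene_id %in% drop)
  expect_equal(attr(m2, "n_excluded"), n_drop)
  expect_equal(sum(m2$analyzed), nrow(fx$ortab$pairs) - n_drop)
  # excluded pairs never surface downstream
  excluded <- m2$pair_id[!m2$analyzed]
  expect_length(intersect(excluded,
                          common_regulated(m2, "up", c("nsSC", "PC", "DC"))),
                0)
  expect_length(intersect(excluded,
                          unlist(unique_expression(m2))), 0)
})

test_that("merging an empty ortholog table warns and yields no rows", {
  fx <- cmp_fixture()
  empty <- fx$ortab
  empty$pairs <- empty$pairs[0, , drop = FALSE]
  expect_warning(m0 <- merge_expression(empty, fx$pa, fx$pb), "empty")
  expect_equal(nrow(m0), 0)
})

test_that("venn3 partitions canonical configurations", {
  s <- sprintf("g%d", 1:6)
  same <- venn3(s, s, s)
  expect_equal(unname(same$counts), c(0, 0, 0, 0, 0, 0, 6))
  disj <- venn3(c("a", "b"), c("c"), c("d", "e", "f"))
  expect_equal(unname(disj$counts), c(2, 1, 3, 0, 0, 0, 0))
})

test_that("venn3 equals brute-force membership enumeration on random sets", {
  set.seed(41)
  pool <- sprintf("g%02d", 1:20)
  for (i in 1:60) {
    a <- sample(pool, sample(0:20, 1))
    b <- sample(pool, sample(0:20, 1))
    cc <- sample(pool, sample(0:20, 1))
    v <- venn3(a, b, cc)
    # brute force: classify every universe element by membership vector
    for (g in unique(c(a, b, cc))) {
      key <- paste0(ifelse(g %in% a, "A", ""), ifelse(g %in% b, "B", ""),
                    ifelse(g %in% cc, "C", ""))
      expect_true(g %in% v$regions[[key]])
    }
    expect_equal(sum(v$counts), length(unique(c(a, b, cc))))
    # regions pairwise disjoint
    all_members <- unlist(v$regions, use.names = FALSE)
    expect_equal(anyDuplicated(all_members), 0)
  }
})

test_that("common regulation requires the call in every population", {
  fx <- cmp_fixture()
  m <- fx$merged
  pops <- c("nsSC", "PC", "DC")
  up3 <- common_regulated(m, "up", pops)
  # membership agrees with the per-column calls
  for (pid in up3) {
    row <- m[m$pair_id == pid, ]
    expect_equal(unname(c(row$ref_call.nsSC, row$query_call.PC,
                          row$query_call.DC)), rep("up", 3))
  }
  # monotone nesting: 3-way within every pairwise within every single
  for (pair in list(c("nsSC", "PC"), c("nsSC", "DC"), c("PC", "DC"))) {
    both <- common_regulated(m, "up", pair)
    expect_true(all(up3 %in% both))
    expect_true(all(both %in% common_regulated(m, "up", pair[1])))
  }
  expect_error(common_regulated(m, "up", "not_a_population"),
               "lookup error")
})

test_that("planted pan-population DE genes are recovered", {
  fx <- cmp_fixture()
  m <- fx$merged
  truth <- fx$sim$truth
  for (dir in c("up", "down")) {
    got <- common_regulated(m, dir, c("nsSC", "PC", "DC"))
    planted <- truth$pairs$pair_id <- paste(truth$pairs$ref_gene_id,
                                            truth$pairs$query_gene_id,
                                            sep = "|")
    lab <- truth$genes_a$de_label[match(truth$pairs$ref_gene_id,
                                        truth$genes_a$gene_id)]
    planted <- planted[lab == dir]
    expect_gt(length(planted), 0)
    expect_gte(mean(planted %in% got), 0.8)
    # and nothing called that was planted the opposite way
    opposite <- truth$pairs$pair_id[lab == setdiff(c("up", "down"), dir)]
    expect_length(intersect(got, opposite), 0)
  }
})

test_that("high-confidence filtering is a flag subset and commutes with intersection", {
  fx <- cmp_fixture()
  ids <- fx$ortab$pairs$pair_id
  all_true <- filter_high_confidence(ids, fx$ortab)
  expect_setequal(all_true, ids[fx$ortab$pairs$high_confidence])
  expect_error(filter_high_confidence(c(ids[1], "zz|zz"), fx$ortab),
               "integrity error")
  set.seed(43)
  for (i in 1:20) {
    a <- sample(ids, sample(length(ids), 1))
    b <- sample(ids, sample(length(ids), 1))
    lhs <- filter_high_confidence(intersect(a, b), fx$ortab)
    rhs <- intersect(filter_high_confidence(a, fx$ortab),
                     filter_high_confidence(b, fx$ortab))
    expect_setequal(lhs, rhs)
  }
})

test_that("unique-expression sets are disjoint and recover planted genes", {
  fx <- cmp_fixture()
  us <- unique_expression(fx$merged)
  ids <- unlist(us, use.names = FALSE)
  expect_equal(anyDuplicated(ids), 0)
  expect_error(unique_expression(fx$merged, cell_types = "HC"),
               "configuration error")

  truth <- fx$sim$truth
  ga <- truth$genes_a
  planted <- ga[!is.na(ga$unique_cell_type) &
                  ga$gene_id %in%
                    fx$merged$ref_gene_id[fx$merged$analyzed], ]
  expect_gt(nrow(planted), 0)
  hits <- vapply(seq_len(nrow(planted)), function(i) {
    pid <- fx$merged$pair_id[fx$merged$ref_gene_id == planted$gene_id[i]]
    any(pid %in% us[[planted$unique_cell_type[i]]])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a gene expressed in two cell types joins no unique set", {
  # construct a merged-like table directly
  fx <- cmp_fixture()
  m <- fx$merged
  two <- m$analyzed & m$ref_mean.nsSC >= 0.10 & m$query_mean.DC >= 0.10
  us <- unique_expression(m, cell_types = c("nsSC", "DC"))
  expect_length(intersect(m$pair_id[two], unlist(us)), 0)
})

test_that("annotation overlays filter by planted TF labels and rank stably", {
  fx <- cmp_fixture()
  m <- fx$merged[fx$merged$analyzed, ]
  truth <- fx$sim$truth
  tf_names <- truth$genes_a$gene_name[truth$genes_a$tf]
  got <- overlay_annotation(m, tf_names)
  expect_setequal(got$pair_id,
                  m$pair_id[m$ref_gene_name %in% tf_names])
  # empty annotation -> empty subset
  expect_equal(nrow(overlay_annotation(m, character(0))), 0)
  # top-N beyond the set returns the whole set sorted by (-lfc, gene id)
  ranked <- overlay_annotation(got, tf_names, rank_by = "ref_lfc.nsSC",
                               top_n = nrow(got) + 50)
  expect_equal(nrow(ranked), nrow(got))
  expect_equal(order(-ranked$ref_lfc.nsSC, ranked$ref_gene_id),
               seq_len(nrow(ranked)))
  # ID-vs-name mismatch triggers the match-rate warning
  expect_warning(overlay_annotation(m, c("definitely", "not", "there")),
                 "match rate")
})
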