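test_that("RPKM follows count * 1e9 / (length * depth)", {
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(100, 1000, 2e6), 50)  # doubling depth halves RPKM
  expect_error(rpkm(10, 0, 1e6), "domain error")
  expect_error(rpkm(10, 1000, 0), "domain error")
})

test_that("count -> RPKM conversion round-trips to the count column", {
  sim <- small_sim()
  m <- sim$matrix_a
  rp <- to_rpkm(m, sim$annotation_a)
  len <- sim$annotation_a$exonic_length[match(m$gene_ids,
                                              sim$annotation_a$gene_id)]
  for (j in seq_len(ncol(m$values))) {
    back <- rp$values[, j] * len / 1e9 * m$library_sizes[[j]]
    expect_equal(back, m$values[, j], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("log2 fold change uses the pseudocount-guarded ratio", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(4, 1, 0.01), log2(4.01 / 1.01))
  expect_equal(log2_fold_change(4, 1, 0.01), 1.989, tolerance = 1e-3)
  expect_equal(log2_fold_change(2e3, 1e3, 1e-6), 1, tolerance = 1e-5)
})

test_that("BH adjustment matches hand step-up values and edge cases", {
  expect_equal(benjamini_hochberg(0.03), 0.03)          # m = 1: q = p
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                            # hand computation
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "domain error")
  expect_error(benjamini_hochberg(c(0.5, -0.1)), "domain error")
})

test_that("BH equals the brute-force step-up on all orderings of small p-sets", {
  base <- c(0.001, 0.02, 0.2, 0.5, 0.8, 0.04)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  for (n in 2:6) {
    for (p in perms(base[seq_len(n)]))
      expect_equal(benjamini_hochberg(p), oracle_bh(p))
  }
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p))
  }
})

test_that("per-gene test matches the classical F test and its conventions", {
  # identical groups with zero variance: p = 1 by convention
  expect_equal(test_gene(c(2, 2, 2), c(2, 2, 2)), 1)
  # zero within-group variance, different means: p = 0 by convention
  expect_equal(test_gene(c(2, 2, 2), c(8, 8, 8)), 0)
  # no effect with spread
  expect_gte(test_gene(c(1, 2, 3), c(1, 2, 3)), 0.99)
  # against stats::aov on the transformed scale
  set.seed(17)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(g) rlnorm(sample(2:5, 1), 1, 1))
    got <- do.call(test_gene, groups)
    y <- log2(unlist(groups) + 0.01)
    f <- factor(rep(seq_len(k), lengths(groups)))
    want <- summary(stats::aov(y ~ f))[[1]][["Pr(>F)"]][1]
    expect_equal(got, want, tolerance = 1e-8)
  }
  expect_error(test_gene(c(1), c(1, 2)), "statistics error")
})

test_that("DE calls keep the asymmetric fold-change boundaries", {
  expect_equal(call_de(1.0, 0.10), "up")          # inclusive >= 1
  expect_equal(call_de(-1.0, 0.01), "unchanged")  # strict < -1
  expect_equal(call_de(-1.000001, 0.01), "down")
  expect_equal(call_de(5, 0.2), "unchanged")      # q above cutoff
  expect_equal(call_de(0.5, 0.01), "unchanged")
  expect_equal(call_de(1.0, 0.05, fdr_cutoff = 0.05), "up")
})

test_that("expressed calls use inclusive RPKM and FDR bounds", {
  vals <- matrix(c(0.10, 0.10, 0.10, 0.09, 0.09, 0.09,
                   5, 6, 7, 1, 1.2, 0.9),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"),
                                 c("X:1", "X:2", "X:3",
                                   "Y:1", "Y:2", "Y:3")))
  m <- expression_matrix(vals, species = "s", reference = "Y",
                         value_kind = "rpkm")
  prof <- run_de(m)
  # force boundary q values to exercise the inclusive FDR clause
  prof$fdr_q[] <- 0.10
  ex <- call_expressed(prof, "X")
  expect_true(ex[["g1"]])    # mean exactly 0.10, q exactly 0.10
  ey <- call_expressed(prof, "Y")
  expect_false(ey[["g1"]])   # mean 0.09 below cutoff regardless of FDR
  expect_true(call_expressed(prof, "X", use_fdr = FALSE)[["g1"]])
  expect_error(call_expressed(prof, "nope"), "lookup error")
})

test_that("run_de output is coherent across contrasts", {
  sim <- small_sim()
  prof <- run_de(sim$matrix_b, sim$annotation_b)
  expect_setequal(unique(prof$contrasts$contrast), c("PC", "DC", "OHC"))
  expect_true(all(prof$contrasts$fdr_q >= 0 & prof$contrasts$fdr_q <= 1))
  up <- prof$contrasts[prof$contrasts$call == "up", ]
  expect_true(all(up$log2fc >= 1 & up$fdr_q <= 0.10))
  down <- prof$contrasts[prof$contrasts$call == "down", ]
  expect_true(all(down$log2fc < -1 & down$fdr_q <= 0.10))
  # mean columns agree with the RPKM matrix
  rp <- to_rpkm(sim$matrix_b, sim$annotation_b)
  ihc <- rowMeans(rp$values[, grepl("^IHC:", colnames(rp$values))])
  sub <- prof$contrasts[prof$contrasts$contrast == "PC", ]
  expect_equal(sub$mean_ref, unname(ihc[sub$gene_id]))
})

test_that("unique-expression genes are planted silent off their cell type", {
  sim <- small_sim()
  rp <- to_rpkm(sim$matrix_a, sim$annotation_a)
  ga <- sim$truth$genes_a
  uniq <- ga[!is.na(ga$unique_cell_type), ]
  expect_gt(nrow(uniq), 0)
  for (i in seq_len(nrow(uniq))) {
    off <- !startsWith(colnames(rp$values),
                       paste0(uniq$unique_cell_type[i], ":"))
    expect_true(all(rp$values[uniq$gene_id[i], off] == 0))
  }
})
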