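write_plain_homology <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("read_homology reads plain and biomart dialects row-for-row", {
  df <- data.frame(ref_gene_id = c("A1", "A1", "A2"),
                   query_gene_id = c("B1", "B1", "B2"),
                   percent_identity = c(60, 60, 40),
                   stringsAsFactors = FALSE)
  got <- read_homology(write_plain_homology(df), dialect = "plain")
  expect_equal(nrow(got), 3)            # duplicates preserved at this stage
  expect_equal(got$ref_gene_id, df$ref_gene_id)
  expect_true(all(is.na(got$goc_score)))

  bm <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    "Gene stable ID" = c("A1", "A2"),
    "Gene name" = c("fam1", "fam2"),
    "Mouse gene stable ID" = c("B1", "B2"),
    "Mouse gene name" = c("Fam1", "Fam2"),
    "Mouse homology type" = c("one2one", "one2one"),
    "%id. target Mouse gene identical to query gene" = c(70.5, 33),
    "Mouse Gene-order conservation score" = c(100, 25),
    "Mouse Whole-genome alignment coverage" = c(88.1, NA),
    "Extra column" = c("x", "y"))
  got <- read_homology(write_plain_homology(bm), dialect = "biomart")
  expect_equal(got$ref_gene_id, c("A1", "A2"))
  expect_equal(got$query_gene_id, c("B1", "B2"))
  expect_equal(got$percent_identity, c(70.5, 33))
  expect_equal(got$goc_score, c(100, 25))
  expect_equal(got[["Extra column"]], c("x", "y"))  # pass-through
})

test_that("read_homology errors name the missing required column", {
  df <- data.frame(ref_gene_id = "A1", percent_identity = 50)
  expect_error(read_homology(write_plain_homology(df), dialect = "plain"),
               "query_gene_id")
})

test_that("read_homology returns an empty list for a header-only file", {
  df <- data.frame(ref_gene_id = character(), query_gene_id = character(),
                   percent_identity = numeric())
  got <- read_homology(write_plain_homology(df), dialect = "plain")
  expect_equal(nrow(got), 0)
})

test_that("transcript-row deduplication keeps first occurrence per gene pair", {
  pairs <- data.frame(
    ref_gene_id = c("A1", "A1", "A1", "A1", "A1"),
    query_gene_id = c("B1", "B1", "B1", "B1", "B2"),
    percent_identity = c(60, 60, 60, 60, 55),
    stringsAsFactors = FALSE)
  got <- deduplicate_transcript_rows(pairs)
  # 4 transcript rows collapse to 1; the paralog edge A1-B2 survives
  expect_equal(nrow(got), 2)
  expect_equal(got$query_gene_id, c("B1", "B2"))
})

test_that("classification matches degree definitions on canonical cases", {
  one <- classify_relationships(data.frame(ref_gene_id = "A1",
                                           query_gene_id = "B1"))
  expect_equal(one$homology_type, "one2one")

  m21 <- classify_relationships(data.frame(
    ref_gene_id = c("A1", "A2"), query_gene_id = c("B1", "B1")))
  expect_equal(m21$homology_type, c("many2one", "many2one"))
  tal <- relationship_tallies(m21)
  expect_equal(tal$many2one[tal$species == "reference"], 2)
  expect_equal(tal$many2one[tal$species == "query"], 1)
})

test_that("classification rejects self-loops, same-species edges and duplicates", {
  expect_error(classify_relationships(data.frame(
    ref_gene_id = "A1", query_gene_id = "A1")), "structural error")
  expect_error(classify_relationships(data.frame(
    ref_gene_id = c("A1", "B1"), query_gene_id = c("B1", "C1"))),
    "structural error")
  expect_error(classify_relationships(data.frame(
    ref_gene_id = c("A1", "A1"), query_gene_id = c("B1", "B1"))),
    "structural error")
})

test_that("classification equals BFS component oracle on random bipartite graphs", {
  set.seed(11)
  for (rep in 1:40) {
    na <- sample(2:15, 1); nb <- sample(2:15, 1)
    ne <- sample(1:25, 1)
    pairs <- unique(data.frame(
      ref_gene_id = sprintf("A%02d", sample.int(na, ne, replace = TRUE)),
      query_gene_id = sprintf("B%02d", sample.int(nb, ne, replace = TRUE)),
      stringsAsFactors = FALSE))
    got <- classify_relationships(pairs)
    expect_equal(got$homology_type, oracle_classify(pairs))
  }
})

test_that("collapsing query redundancy gives distinct-gene counts per side", {
  pairs <- data.frame(ref_gene_id = c("A1", "A2"),
                      query_gene_id = c("B1", "B1"))
  got <- collapse_query_redundancy(pairs)
  expect_equal(got$n_ref, 2)
  expect_equal(got$n_query, 1)

  one <- data.frame(ref_gene_id = c("A1", "A2"),
                    query_gene_id = c("B1", "B2"))
  expect_equal(collapse_query_redundancy(one)$n_ref,
               collapse_query_redundancy(one)$n_query)
})

test_that("tallies are consistent with pairs and universes (table structure)", {
  sim <- simulate_genomes(sim_config(n_base_genes = 200, seed = 9))
  ortab <- build_ortholog_table(sim$homology, sim$annotation_a,
                                sim$annotation_b)
  tal <- ortab$tallies
  # ortholog total + unique genes = protein-coding total, per species
  expect_equal(tal$total_orthologs + tal$unique_genes,
               tal$total_protein_coding)
  # class tallies recomputable from pairs
  for (sp in c("reference", "query")) {
    ids <- if (sp == "reference") ortab$pairs$ref_gene_id else
      ortab$pairs$query_gene_id
    for (cl in c("one2one", "many2one", "many2many"))
      expect_equal(tal[[cl]][tal$species == sp],
                   length(unique(ids[ortab$pairs$homology_type == cl])))
  }
  # reference >= query ortholog totals (query redundancy collapsed)
  expect_gte(tal$total_orthologs[1], tal$total_orthologs[2])
})

test_that("WGA score follows the exon-weighted averaged-coverage formula", {
  expect_equal(wga_score(1, 1, 1, 1), 100)
  expect_equal(wga_score(0, 0, 0, 0), 0)
  expect_equal(wga_score(0.8, 0.4, 0.8, 0.4, exon_weight = 0.75), 70)
  # asymmetric genes average
  expect_equal(wga_score(1, 1, 0, 0), 50)
  expect_error(wga_score(1.2, 0, 0, 0), "domain error")
  expect_error(wga_score(0.5, 0.5, 0.5, 0.5, exon_weight = 0.4),
               "domain error")
})

test_that("high-confidence rule: %ID >= 50 and (GOC >= 75 or WGA >= 75)", {
  expect_true(call_high_confidence(60, 100, NA))   # and/or with missing WGA
  expect_false(call_high_confidence(49, 100, 100)) # %ID clause fails
  expect_true(call_high_confidence(50, 75, 0))     # inclusive boundaries
  expect_false(call_high_confidence(50, NA, NA))   # both missing
  expect_true(call_high_confidence(50, NA, 75))
})

test_that("high-confidence is monotone in every score", {
  set.seed(21)
  for (i in 1:200) {
    pid <- runif(1, 0, 100)
    goc <- sample(c(NA, 0, 25, 50, 75, 100), 1)
    wga <- sample(c(NA, runif(1, 0, 100)), 1)
    base <- call_high_confidence(pid, goc, wga)
    bump <- function(x, d) if (is.na(x)) x else min(100, x + d)
    expect_true(!base ||
                  (call_high_confidence(min(100, pid + 10), goc, wga) &&
                     call_high_confidence(pid, bump(goc, 25), wga) &&
                     call_high_confidence(pid, goc, bump(wga, 10))))
  }
})
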