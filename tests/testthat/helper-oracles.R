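# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately share no code with R/.

# gene-order conservation by explicit neighborhood enumeration
oracle_goc <- function(gene, partner, pairs, ann_a, ann_b, window = 2) {
  map <- list()
  for (i in seq_len(nrow(pairs)))
    map[[pairs$ref_gene_id[i]]] <- c(map[[pairs$ref_gene_id[i]]],
                                     pairs$query_gene_id[i])
  ordered <- function(ann, keep) {
    sub <- ann[ann$gene_id %in% keep, ]
    sub <- sub[order(sub$chromosome, sub$start, sub$gene_id), ]
    split(sub$gene_id, sub$chromosome)
  }
  ord_a <- ordered(ann_a, names(map))
  ord_b <- ordered(ann_b, unique(pairs$query_gene_id))
  nbrs <- function(ord, g) {
    for (chr_genes in ord) {
      i <- which(chr_genes == g)
      if (length(i) == 1) {
        lo <- max(1, i - window); hi <- min(length(chr_genes), i + window)
        return(setdiff(chr_genes[lo:hi], g))
      }
    }
    character(0)
  }
  nb <- nbrs(ord_a, gene)
  win <- nbrs(ord_b, partner)
  matched <- 0
  for (g in nb) if (any(map[[g]] %in% win)) matched <- matched + 1
  100 / (2 * window) * matched
}

# relationship classes by breadth-first component search
oracle_classify <- function(pairs) {
  rn <- paste0("R:", pairs$ref_gene_id)
  qn <- paste0("Q:", pairs$query_gene_id)
  nodes <- unique(c(rn, qn))
  adj <- lapply(seq_along(nodes), function(i) character(0))
  names(adj) <- nodes
  for (i in seq_len(nrow(pairs))) {
    adj[[rn[i]]] <- c(adj[[rn[i]]], qn[i])
    adj[[qn[i]]] <- c(adj[[qn[i]]], rn[i])
  }
  comp <- rep(NA_integer_, length(nodes))
  names(comp) <- nodes
  cid <- 0
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  deg <- lengths(adj)
  cls <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    members <- names(comp)[comp == comp[rn[i]]]
    mr <- any(deg[members[startsWith(members, "R:")]] > 1)
    mq <- any(deg[members[startsWith(members, "Q:")]] > 1)
    cls[i] <- if (mr && mq) "many2many" else
      if (mr || mq) "many2one" else "one2one"
  }
  cls
}

# step-up BH by direct definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# upper-tail hypergeometric by summing binomial-coefficient products
oracle_hyper <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# random paired toy genomes + ortholog map for GOC oracle testing
random_goc_case <- function(n_genes = 12, n_chrom = 2) {
  mk <- function(prefix) {
    data.frame(
      gene_id = sprintf("%s%02d", prefix, seq_len(n_genes)),
      gene_name = sprintf("%s%02d", prefix, seq_len(n_genes)),
      chromosome = sample(paste0("c", seq_len(n_chrom)), n_genes,
                          replace = TRUE),
      start = sample.int(10000, n_genes),
      stringsAsFactors = FALSE
    )
  }
  ann_a <- mk("A")
  ann_b <- mk("B")
  # random many-to-one-capable map over a random subset
  n_edges <- sample(3:(2 * n_genes), 1)
  pairs <- unique(data.frame(
    ref_gene_id = sample(ann_a$gene_id, n_edges, replace = TRUE),
    query_gene_id = sample(ann_b$gene_id, n_edges, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  list(ann_a = ann_a, ann_b = ann_b, pairs = pairs)
}

# small deterministic annotation builder for fixtures: genes laid out in
# the order given, one chromosome name per element of `chrom`
make_annotation <- function(gene_ids, chrom) {
  n <- length(gene_ids)
  ann <- data.frame(
    gene_id = gene_ids,
    gene_name = gene_ids,
    chromosome = chrom,
    start = as.integer(stats::ave(seq_len(n), chrom, FUN = seq_along) * 1000L),
    stringsAsFactors = FALSE
  )
  ann$end <- ann$start + 500L
  ann$strand <- "+"
  ann$transcript_count <- 1L
  ann$exonic_length <- 500
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

small_sim <- function(...) {
  cfg <- sim_config(n_base_genes = 250, seed = 42, ...)
  sim <- simulate_genomes(cfg)
  expr <- simulate_expression(cfg, sim$annotation_a, sim$annotation_b,
                              sim$truth)
  c(sim, expr, list(config = cfg))
}
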