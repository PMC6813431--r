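---
title: "Comparing cell-type expression programs across species through orthology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cell-type expression programs across species through orthology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoexpr)
```

## The problem

Non-mammalian vertebrates such as zebrafish regenerate inner-ear hair cells
from surrounding supporting cells; mammals do not. A natural way to look
for the regulators behind that difference is to compare the expression
programs of supporting cells (zebrafish non-sensory supporting cells,
nsSCs; mouse pillar and Deiters' cells, PCs and DCs) against their
species' hair cells (zebrafish HCs; mouse inner and outer hair cells, IHCs
and OHCs) — but the two species' measurements live on different genomes,
so every comparison must pass through an ortholog map, and the quality of
each ortholog assignment must itself be scored.

`orthoexpr` implements that workflow as a reusable pipeline: build and
confidence-score an ortholog table, call expressed and differentially
expressed genes per species against its reference hair-cell type, merge
the two species' results by orthology, and compute the shared/unique gene
sets with optional annotation overlays and over-representation tests.
Because genome-scale inputs are large and external, the package ships a
paired-genome simulator that emulates the downstream products of such a
study — annotations, a homology export, replicate expression tables —
with planted ground truth, so every stage is testable end to end.

## Ortholog confidence scoring

Three quantities score each reference–query gene pair.

**Percent identity** is taken from the homology export as given.

**Gene-order conservation (GOC)** asks whether the two genes upstream and
two genes downstream of the target gene have their orthologs near the
partner gene. Each of the (at most four) neighbors contributes 25 when any
of its orthologs lies within the partner's own two-up/two-down
neighborhood, so the score lies on the lattice {0, 25, 50, 75, 100} and
100 means all four neighbors are conserved. Two design choices deserve
emphasis:

* *Neighborhoods are formed on the ortholog-bearing gene order.* Genes
  with no ortholog in the partner species are skipped when counting the
  two positions either side. This matches how gene-order conservation is
  meaningfully defined over an orthology map — a species-specific gene
  interleaved between two conserved genes says nothing about synteny decay
  — and it makes the score robust to lineage-specific gene gain.
* *Chromosome ends keep the denominator at four.* A gene one position from
  the end of its chromosome has at most three candidate neighbors; the
  missing ones count as non-matches, keeping the score on the same
  lattice. Strand is ignored.

With a neighbor declared conserved by *window membership* (any ortholog
anywhere in the partner's 2+2 window, not only the mirrored position),
many-to-one orthologs are handled naturally: any copy in the window
counts.

**Whole-genome alignment coverage (WGA)** is, per gene, an exon-weighted
mean of exon and intron alignment coverage scaled to 0–100, and per pair
the arithmetic mean of the two genes' scores. The exon weight defaults to
0.75 (exons must weigh more than introns; the exact weight is exposed as a
parameter). The simulator draws WGA scores directly rather than computing
them from sequence — no sequences are simulated — while the formula itself
is unit-tested separately.

**High confidence** combines the three: percent identity ≥ 50 *and* (GOC
≥ 75 *or* WGA ≥ 75), all bounds inclusive. A missing score fails its
clause; a pair with both GOC and WGA missing is never high-confidence.
This is the conservative reading — it cannot inflate the high-confidence
set — and it makes the call monotone in every score.

## Relationship classes

Homology classes are not trusted from the input; they are recomputed from
the bipartite graph of deduplicated pairs. Within a connected component:
all degrees 1 → `one2one`; genes of degree > 1 on exactly one side →
`many2one`; on both sides → `many2many`. Per-species tallies count
distinct genes per class, and distinct-gene counting (rather than edge
counting) is what makes the two species' many-to-one tallies differ, as
they do in real zebrafish–mouse tables where zebrafish paralog groups map
onto single mouse genes. Each species' ortholog total plus its
species-unique genes equals its protein-coding total, which the table
asserts.

Biomart-style exports repeat each pair once per reference transcript;
`deduplicate_transcript_rows()` keeps the first occurrence of each
`(ref, query)` pair. Scores are identical across transcript rows in such
exports, so which occurrence is kept is immaterial.

## Expression calling

Counts are normalized as RPKM: `count × 1e9 / (exonic length × library
size)`, with the exonic length taken as the length of the union of all
exon intervals across a gene's transcripts (computed from the GTF).

Per-gene testing is a one-way ANOVA across the species' cell types on
`log2(RPKM + pseudocount)` (pseudocount 0.01 RPKM by default), followed by
Benjamini–Hochberg adjustment across genes. The upstream study obtained
FDR-adjusted p-values from a commercial pipeline's two-way ANOVA whose
factors are not recoverable from the text; the one-way ANOVA across cell
types is the package's own, reproducible substitute. The thresholds
applied downstream — the substance of the analysis — are unchanged. For
two groups the test reduces to the equal-variance t-test. Degenerate
inputs follow a fixed convention: zero variance with equal means gives
p = 1, zero within-group variance with unequal means gives p = 0. The
statistic is computed by vectorized sums of squares for speed across
thousands of genes and is checked against `stats::aov` in the tests.

Calls use inclusive/exclusive conventions exactly as stated in the
motivating analysis:

* **expressed**: mean replicate RPKM ≥ 0.10 *and* gene FDR ≤ 0.10 (both
  inclusive). Applying a DE-derived FDR to an expression call is unusual;
  a flag allows RPKM-only calling.
* **up**: log2 fold change ≥ +1.0 (inclusive) with FDR ≤ cutoff;
  **down**: log2 fold change < −1.0 (strict). The asymmetry is preserved
  deliberately.
* The FDR cutoff is a per-analysis parameter (0.10 for the main DE
  analysis, 0.05 for transcription-factor rankings), not a constant.
* Replicates are aggregated by the arithmetic mean of RPKM.

## Cross-species merging and set algebra

`merge_expression()` inner-joins the two species' profiles on the
ortholog table, one row per pair. Pairs lacking expression data in either
species are kept but flagged and excluded from all set analyses. The two
species' RPKM values are never rescaled onto a single scale — they come
from different genomes and library preparations and are not quantitatively
equivalent; all cross-species statements are at the level of calls.

Set keys are ortholog-pair IDs (`ref|query`), not gene names, so
many-to-one mappings cannot collapse distinct pairs. On top of the merged
table the package provides the exact 7-region Venn partition of three
sets, common-regulated sets (call equal in every listed population's
contrast), high-confidence filtering (which commutes with intersection),
the unique-expression caller (expressed in exactly one of the supplied
cell types; the mouse contrasts use IHC as the sole reference, while OHC
participates in unique-expression analysis only), and annotation overlays
(transcription-factor or deafness-gene lists, matched by ID or name with
automatic key-style detection, ranked by descending log2 fold change with
gene-ID tie-breaks). The unique-expression caller applies the plain
RPKM-cutoff rule to cell-type means; cell types can be included or
excluded by configuration, so control tissues can be kept out of the
analysis.

Over-representation of result sets against GMT collections uses the
one-sided hypergeometric upper tail with a user-declared universe
(defaulting to all analyzed pairs), BH-adjusted across the collection.
This is a functional stand-in for interactive GO tools, not a numerical
reproduction of any of them; GO hierarchies are out of scope.

## The simulator

`simulate_genomes()` builds both annotations from `n_base_genes` ancestral
genes: a base gene is species-unique (orphan) with the configured
probabilities, otherwise conserved; conserved genes are duplicated in
species A with probability `paralog_expansion_prob` (tandem placement,
producing many-to-one components) and independently in species B with a
smaller probability (producing many-to-many components when both fire).
Conserved genes occupy syntenic neighborhoods; a configured fraction of
species-B genes is relocated to random positions, which degrades GOC
through the full lattice. Rearrangement is random relocation, not
inversion — sufficient to produce every GOC value. Orphans get no homology
edge and appear as species-unique genes in the tallies.

`simulate_expression()` draws per-gene baseline RPKM from a log-normal
(default meanlog 1.5, sdlog 1.2 on the natural-log scale, i.e. a median
around 4.5 RPKM with a realistic right tail), applies planted effects, and
samples negative-binomial counts around length- and depth-scaled means.
Counts (not RPKM) are emitted so the normalization path is exercised end
to end. Planted structure lives on conserved base genes: DE labels
(up/down vs the reference type, shifted by ±`log2fc_effect` in all
non-reference cell types of both species, so pan-population recovery is
well-defined), unique-expression genes (non-zero in exactly one of the
combined cell types, zero everywhere else in both species), and
transcription-factor flags. Replicate-level dispersion defaults
(`nb_dispersion = 0.05`, i.e. NB size 20) are free parameters chosen to
resemble bulk sorted-cell RNA-seq; no published replicate variance was
available to calibrate them.

What the simulator does *not* emulate: sequence evolution (WGA is drawn,
not computed), realistic chromosome-scale synteny blocks, isoform-level
expression, batch effects, or cross-species count correlation. Passing
recovery tests therefore demonstrates the pipeline's correctness on data
satisfying its model, not robustness to every artifact of real data.

Everything is seeded: the same configuration (including `seed`) yields
byte-identical outputs; expression uses a second stream derived from
`seed + 1` so genomes and expression can be regenerated independently.

## Numerical choices and degenerate inputs

* Sums-of-squares comparisons use a relative tolerance
  (`1e-10 × (1 + Σx²)`) to detect zero-variance rows.
* Ordering is always `(chromosome, start, gene_id)` with the gene ID as a
  deterministic tie-break; every output TSV has a header and documented
  sort keys, and the pipeline manifest records row counts and a
  configuration hash so identical inputs give identical outputs.
* An empty ortholog table merges to an empty table with a warning; empty
  annotation files warn and return empty annotations; genes without exon
  features are skipped with a warning.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the
  hypergeometric tail to `stats::phyper`; connected components to
  `igraph`. Each is validated against an independent brute-force oracle in
  the tests.

## Problem sizes in the test suite

The shipped tests run the simulator at a few hundred base genes with 3–5
replicates, sizes at which every planted signal is comfortably
identifiable and the full suite runs in about a minute. Recovery tests
use a sharper configuration (effect 3 log2 units, 5 replicates, NB
dispersion 0.01) for recall/precision checks, and 20 independent null
simulations for FDR calibration. These sizes are the package's chosen
validation conditions, two orders of magnitude below a genome-scale run,
which the same code handles by construction (all per-gene operations are
vectorized).

## Known limitations

* The per-gene test is a fixed-effects ANOVA on log RPKM, not a count
  model; with two replicates per group it is underpowered, and no
  moderation across genes is attempted.
* GOC ties to annotation completeness: a sparsely annotated partner
  chromosome inflates neighborhood conservation.
* The high-confidence rule treats the input percent identity as
  authoritative; the package never recomputes it from sequence.
* Enrichment assumes an exchangeable universe; gene-length or expression
  biases are not corrected.
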