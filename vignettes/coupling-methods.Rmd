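---
title: "Cell-type-resolved receptor coupling scores: models and design choices"
author: "scCoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved receptor coupling scores: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scCoupling)
```

## The scientific problem

Corticosteroid signaling in the hippocampus is carried by two nuclear
receptors — the glucocorticoid receptor GR (*Nr3c1*) and the
mineralocorticoid receptor MR (*Nr3c2*) — whose downstream effects depend
on which other genes are co-expressed with them in each cell type: sex
hormone receptors, transcriptional coregulators, neurotransmitter and
neuropeptide receptors, and the receptors' own target genes. scCoupling
quantifies this cell-type-resolved co-expression from single-cell RNA-seq
and integrates independent transcriptomic and ChIP-seq evidence into a
conservative list of receptor target genes.

The package operates on a labeled sparse count matrix (genes × cells with a
cell-type annotation, e.g. the 13 hippocampal subclasses: Astro, Oligo,
Endo, Micro-PVM, Lamp5, Vip, Pvalb, Sncg, Sst, DG, CA1-ProS, CA2, CA3) and
proceeds in five stages: preprocessing, cell-type profiling, coupling
scores, consensus target calling, and marker statistics. A seeded simulator
provides labeled data with planted ground truth for every stage.

## Preprocessing

Quality control removes cells detecting fewer than `minFeatures` genes
(default 100) and then genes detected in fewer than `minCells` retained
cells (default 1). The cells-then-genes order mirrors the creation-time
semantics of the usual loading parameters; at `minCells = 1` the operation
is idempotent, because a gene detected in zero retained cells cannot
contribute to any cell's detected-gene count. For `minCells > 1` strict
idempotence is not guaranteed and the removal counts are recorded in the
object metadata instead.

Normalization is the standard library-size scaling with log transform,

$$ y_{gc} = \ln\!\left(1 + n_{gc}\,\frac{s}{N_c}\right), $$

with scale factor $s = 10{,}000$ by default. Zeros map to zeros exactly, so
sparsity is preserved; the transform is monotone within a cell and
invariant to rescaling a cell's counts. Cells with zero totals are rejected
with a pointer to QC, rather than silently propagating `NaN`.

Highly-variable-gene ranking (`selectVariableGenes()`, a
variance-stabilizing loess of log-variance on log-mean with clipped
standardized values) is provided for parity with common pipelines, but no
downstream stage depends on it: coupling and profiling operate on *named*
gene sets, so unsupervised feature selection never changes a reported
quantity. Note the ranking is only as good as the mean-variance trend it
can estimate: with few genes, or genes isolated in their mean regime, the
trend absorbs real structure.

## Cell-type profiles

`aggregateProfile()` computes, per gene $i$ and cell type $t$, the
arithmetic mean $x_{it}$ of log-normalized expression and the
percent-positive (share of cells with raw count > 0, 0–100). Percent-
positive is deliberately computed on raw counts, making it invariant to the
normalization parameters. Group columns follow the canonical hippocampal
subclass order when labels permit, else lexicographic order, so heatmap and
table layouts are reproducible. `scoreProfile()` adds row z-scores over
groups (sample SD; rows constant across groups get all-zero z rather than
`NaN`). `splitBy()` crosses annotation keys (e.g. cell type × sex) into a
composite grouping for profiles stratified by sex.

## The coupling score

For a receptor $j$ and every gene $i$ of a curated set $S$ in cell type
$t$:

$$ k_{ijt} = \log_{10}(x_{it}\, x_{jt}), \qquad
   C^{S}_{ijt} = \frac{k_{ijt} - \min_S k}{\max_S k - \min_S k}. $$

$k$ is symmetric in $i$ and $j$ and increases with either average;
multiplying all averages by $a$ shifts every $k$ by $2\log_{10} a$ and
leaves $C$ unchanged, so $C$ ranks co-expression *within* a set without
units. Numerical choices:

* **Zero averages.** $\log_{10} 0$ is undefined, so averages are floored at
  `epsilon` $= 10^{-6}$ before the product. A gene absent from a cell type
  therefore lands at the block minimum rather than $-\infty$, matching the
  expectation that unexpressed genes (e.g. *Esr1*/*Esr2* in most
  hippocampal cells) produce very low coupling.
* **Normalization scope.** The min and max are taken over the whole
  (gene ∈ S) × (cell type) grid per receptor — the scope consistent with
  heatmaps sharing one color scale across cell types. The subscript
  convention could equally be read per cell type, so `scope = "per_group"`
  is available; the default is the grid.
* **Degenerate blocks.** If a block is constant, $C$ is defined as all
  zeros (no co-expression contrast, no division by zero).
* **Input choice.** $x$ is the mean of log-normalized values, consistent
  with the profile definition upstream; a sensitivity analysis on de-logged
  means can be run by building the profile from a different assay.

`shortlistCoupling()` selects (gene, cell type) pairs with $C > 0.6$
(strict inequality). The phrase "above threshold with both receptors or
either" is genuinely ambiguous in the field's usage, so the rule is
explicit: the default `"either"` keeps pairs passing for at least one
receptor and annotates which, `"both"` requires all receptors. No
significance is attached to coupling scores — the statistic is a ranking,
not a test — which is also why normalized scores are never compared across
gene sets.

## Consensus target genes

`applyConsensus()` implements the multi-evidence filter on a per-gene,
per-study evidence table: a gene is called a GR/MR target iff

1. it was regulated by glucocorticoids in the published meta-analysis
   (≥ 1 `meta_transcriptomic` row);
2. it responded in the in-house hippocampal RNA-seq (`inhouse_rnaseq` row);
3. the direction of regulation is identical in *all* reporting
   transcriptomic studies;
4. it carries a GR and/or MR ChIP-seq binding annotation.

A fifth, enabled-by-default rule requires reports from at least three
distinct transcriptomic studies (`minReportingStudies = 3`). The source
text is ambiguous about whether "reported in at least three studies" is a
filter or a description of the survivors; treating it as a configurable
filter (set it to 1 to disable) covers both readings, and because the
criteria are conjunctive the application order cannot change the final
call set — only intermediate funnel counts, which `summarizeEvidence()`
reports explicitly. Reporting-study counts include the in-house study and
never ChIP-seq studies. Binding classes are unions over ChIP-seq rows
(GR-only, MR-only, or both). Gene symbols are matched case-sensitively
after whitespace trimming, with no orthology mapping: cross-species
evidence (mouse/rat) is combined by symbol on the grounds that functional
glucocorticoid response elements tend to be evolutionarily conserved.

## Rank statistics

Marker detection (`findGroupMarkers()`) is the one-vs-rest Wilcoxon
rank-sum test per gene and cell type with Benjamini–Hochberg adjustment
over all hypotheses of the run (the adjustment scope is a choice; it is
recorded in the output rather than assumed). Pre-filters — expression in at
least 10 % of cells on one side and |log2 FC| ≥ 0.25 — default to the
documented conventions of the mainstream toolkit, since the procedure is
usually run unparameterized; `prefilter = FALSE` disables them for
exhaustive cross-checks.

Both rank tests are implemented in the package. Exactness policy: the
signed-rank test enumerates its null for ≤ 25 tie-free nonzero differences,
the rank-sum test for combined n ≤ 50 without ties; otherwise a normal
approximation with tie correction and 0.5 continuity correction is used.
Zero differences are dropped with the usual reduction of n; an all-zero
contrast returns p = 1. The fold change defaults to
$\log_2\frac{\overline{e^{a}-1}+1}{\overline{e^{b}-1}+1}$ (de-log, average,
pseudocount 1) because the source convention for printed fold changes is
not stated; the difference-of-log-means variant is available via
`fcMode = "logdiff"`, and neither is asserted to be the convention behind
any particular published number. The same caveat applies to the paired
contrast across cell types: `pairedGeneContrast()` pairs the 13 per-type
averages, `geneWithinGroupContrast()` pools cells within one type, and both
modes are exposed because published per-gene p-values could arise from
either.

## What the simulator emulates — and what it does not

`simulateCounts()` draws counts from a negative binomial with variance
$\mu + \mu^2/\phi$ (size $\phi$, default 1), per-gene log-normal base means
around `baseMean` (default 0.2 counts, a typical droplet depth), and
per-cell log-normal library-size factors (σ = 0.3, expectation 1). Two
designated receptor genes follow fixed per-group multiplier profiles
(*Nr3c2*-like enrichment in glutamatergic neurons, *Nr3c1*-like broad
expression highest in non-neuronal types), and planted pairs multiply both
genes' means by `fold` in one group, giving coupling recovery tests an
exact ground truth (the realized mean matrix is stored in the object
metadata). The default scale — 13 groups × 200 cells × 2,000 genes — is a
desk-scale stand-in for a portal-scale atlas (tens of thousands of cells,
26k genes); validation runs in this package use 60–300 genes and 13 × 200
cells, sizes chosen so that the full suite re-runs in minutes.

Deliberately not simulated: doublets, ambient RNA, batch effects, dropout
beyond NB sampling, taxonomy hierarchies, and realistic gene-gene
correlation beyond the planted pairs. Passing tests therefore demonstrate
algorithmic correctness and recovery of planted signal under NB noise —
not robustness to the artifacts of real droplet data.

`simulateEvidence()` generates evidence tables with labeled truth: true
targets satisfy all criteria (including ≥ 3 reporting studies), and each
decoy violates exactly one of the four core criteria. A gene absent from
the meta-analysis necessarily also falls below the three-study rule, since
only one in-house study exists — an arithmetic consequence, not a
simulation choice. Defaults mirror the published funnel composition
(19 targets, 15 up / 4 down, binding 14 GR / 1 MR / 4 both, 17
meta-analysis studies).

## Known limitations

* The coupling score inherits the biases of averages over heterogeneous
  groups: a small subpopulation co-expressing both genes is invisible.
* Min–max normalization makes $C$ relative to the set: adding or removing
  set members rescales every score in the block.
* Consensus calling consumes binding annotations as given; peak-to-gene
  assignment distance rules of the underlying ChIP-seq studies are outside
  its scope, as are the meta-analysis and differential-expression steps
  that generate the transcriptomic evidence rows.
* Group labels are consumed as given; no clustering or label transfer is
  performed.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  simulate = list(nGroups = 13, cellsPerGroup = 100, nGenes = 500,
                  seed = 1,
                  plantedPairs = list(list(geneA = "Nr3c1",
                                           geneB = "Gene0100",
                                           group = "DG", fold = 50))),
  minFeatures = 10,
  geneSets = list(demo = sprintf("Gene%04d", seq(50, 500, by = 50)),
                  receptors = c("Nr3c1", "Nr3c2")),
  markers = TRUE
)
res <- runPipeline(cfg, "demo_run")
head(couplingRecords(res$coupling$demo))
res$shortlists$demo
```
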