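# scCoupling

Cell-type-resolved co-expression of nuclear receptors in single-cell
RNA-seq, built around the corticosteroid receptors of the hippocampus.

## What it does, and for whom

Glucocorticoid and mineralocorticoid receptor signaling (GR, *Nr3c1*; MR,
*Nr3c2*) depends on which partner genes — sex hormone receptors,
coregulators, neurotransmitter/neuropeptide receptors, target genes — are
expressed *in the same cell type*. scCoupling is for transcriptomics
researchers who have a labeled sparse count matrix (e.g. a brain-atlas
export with cell-type subclasses) and want to:

1. build per-cell-type expression profiles (average log-normalized
   expression `x_it`, percent-positive, z-scores);
2. rank receptor/gene co-expression across cell types with the **coupling
   score**

   ```
   k_ijt = log10(x_it * x_jt)
   C_ijt^S = (k_ijt - min_S k) / (max_S k - min_S k)
   ```

   normalized within a curated gene set `S`, and shortlist pairs with
   `C > 0.6`;
3. call **consensus target genes** from a per-gene, per-study evidence
   table: reported in a published meta-analysis, responsive in an in-house
   RNA-seq experiment, direction-consistent across all reporting studies,
   backed by GR/MR ChIP-seq binding, and reported by ≥ 3 transcriptomic
   studies;
4. compute one-vs-rest Wilcoxon marker statistics with BH adjustment, and
   paired/within-type gene contrasts with exact small-sample p-values.

A seeded negative-binomial simulator (13 hippocampal subclasses by
default, planted co-expression pairs, evidence tables with known truth)
makes every stage testable end to end without any download. The data
containers are Bioconductor native: `SingleCellExperiment` in, S4
`TypeProfile` / `CouplingResult` objects out.

## Worked example

```r
library(scCoupling)

cfg <- simConfig(nGroups = 13, cellsPerGroup = 100, nGenes = 500, seed = 1,
                 plantedPairs = list(list(geneA = "Nr3c1", geneB = "Gene0100",
                                          group = "DG", fold = 50)))
sce <- simulateCounts(cfg)
sce <- logNormalize(qcFilter(sce, minCells = 1, minFeatures = 10))
profile <- scoreProfile(aggregateProfile(sce))
profile
#> TypeProfile: 500 genes x 13 groups (grouped by 'group')
#>  groups: Astro, Oligo, Endo, Micro-PVM, Lamp5, Vip, Pvalb, Sncg, Sst, DG, CA1-ProS, CA2, CA3
#>  cells : 1300 total
#>  z     : filled

res <- couplingScore(profile, receptors = c("Nr3c1", "Nr3c2"),
                     geneSet = sprintf("Gene%04d", seq(50, 500, by = 50)),
                     setName = "demo")
rec <- couplingRecords(res)
sub <- subset(rec, gene == "Gene0100" & receptor == "Nr3c1")
head(sub[order(-sub$cNorm), ], 3)
#>  receptor     gene     group           k     cNorm  set
#>     Nr3c1 Gene0100        DG  1.47163570 1.0000000 demo
#>     Nr3c1 Gene0100     Astro -0.03078742 0.7954086 demo
#>     Nr3c1 Gene0100 Micro-PVM -0.04674847 0.7932351 demo
```

The pair planted in the dentate gyrus (fold 50) tops the normalized
coupling scale exactly there: `C = 1` in DG, with every other cell type
well below. `shortlistCoupling(res, threshold = 0.6)` returns the (gene,
cell type) pairs exceeding the cutoff with the passing receptors
annotated per row.

Consensus target calling on a simulated evidence table (defaults emulate
the published GR/MR evidence funnel):

```r
ev <- simulateEvidence(evidenceSimConfig(seed = 1))
calls <- applyConsensus(ev$evidence)
nrow(calls)
#> [1] 19
table(calls$direction)        # 15 up, 4 down
table(calls$binding_class)    # 14 GR, 1 MR, 4 both
head(calls[, c("gene", "direction", "binding_class", "n_reporting_studies")], 4)
#>    gene direction binding_class n_reporting_studies
#>  Tgt001        up            GR                   3
#>  Tgt002        up            GR                   3
#>  Tgt003        up            GR                   5
#>  Tgt004        up            GR                   3
```

19 genes survive all criteria — 15 consistently up-, 4 down-regulated;
14 with GR-specific binding, 1 MR-specific, 4 with both — and each decoy
engineered to break one criterion is rejected. A paired contrast of the
two receptors across the 13 cell-type averages:

```r
pairedGeneContrast(profile, "Nr3c1", "Nr3c2")
#>  gene_a gene_b   log2fc          p      p_adj                 test
#>   Nr3c1  Nr3c2 3.289711 0.09423828 0.09423828 wilcoxon_signed_rank
```

`runPipeline()` chains all stages from one (YAML-able) configuration and
writes profile, coupling, shortlist, consensus and marker TSVs plus a
manifest; `inst/scripts/run_pipeline.R` wraps it for the shell.

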