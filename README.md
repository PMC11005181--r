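# chromlink

Separating developmental from housekeeping gene-regulatory programs in
three-lineage (ectoderm / endoderm / mesoderm) pseudo-bulk multi-omic data:
transcriptome, GpC chromatin accessibility and CpG DNA methylation, plus TAD
annotations and enriched transcription-factor motif lists.

The package is aimed at regulatory genomicists working with joint
single-cell multi-omic assays (scNMT-seq / NOMe-seq style) aggregated to
pseudo-bulk per germ layer, who want to contrast lineage-specific
(developmental) and lineage-invariant (housekeeping) regulation.

## The statistics at its core

**Dominance classification.** For a gene with linear-scale expression
(GE1, GE2, GE3), the Berger-Parker dominance index is

    Dom = max(GEi) / sum(GEi),   Dom in [1/3, 1]

A gene is a lineage-specific **DEG** when Dom >= 0.6 (and the dominant
lineage is expressed, log2 RPKM > 2), a **SEG** (similarly expressed,
housekeeping-like) when Dom <= 0.34 with all lineages expressed; an even
triple gives Dom = 0.33. The same statistic applied to per-window
accessibility levels calls **DARs** vs **SARs** (100-bp windows), and
applied to per-window hypomethylation (1 - M) calls **DhMRs** vs **ShMRs**
(500-bp windows). Threshold significance is assessed by permutation tests
that assemble random expression triples per lineage, with
p = (k + 1)/(n + 1) and 0 hits in 1000 permutations reported as 0.001.

**CAC linking.** For a gene set, the chromatin abundance coefficient is the
Pearson correlation between the normalised open-region frequency around
each TSS, f_i = N(V_i)/Ng(V_i) (region centres within a +/-V vicinity over
expressed genes in it), and the mean expression of genes grouped by f. The
zone of maximal influence Z* = argmax_V CAC(V) over a grid of vicinities is
then the linking radius: a DAR is linked to a DEG when their distance is at
most Z* **and** both lie in the same TAD — links never cross TAD
boundaries. Genome/TAD architecture statistics (nearest-expressed-TSS
distances, TAD gene density, DEG/SEG co-occurrence) and motif-repertoire
comparisons (quartile-rank vectors over a shared motif union, RMSE to the
line y = x, GC-stratified rank permutations, dinucleotide entropy)
complete the pipeline.

A synthetic multi-omic generator (`simulationSpec()` / `generateDataset()`)
plants all of this structure with known ground truth, so every stage is
testable without downloads.

## Worked example

```r
library(chromlink)

ds <- generateDataset(simulationSpec(seed = 1))
cl <- classifyGenes(ds$expression)
table(cl$class_label)
#> DEG_ectoderm DEG_endoderm DEG_mesoderm          SEG unclassified
#>           29           30           28           90          143

acc     <- windowLevels(ds$accWindows)
qc      <- qcFilter(acc)                       # 3615 -> 3258 windows
regions <- callAccessibilityRegions(qc$windows)
table(regions$region_class)
#>    DAR SAR_HA SAR_LA
#>   2482      3      2

ann       <- ds$annotation
deg       <- ann[ann$gene_id %in% cl$gene_id[cl$class_label == "DEG_ectoderm"]]
expressed <- ann[ann$gene_id %in% cl$gene_id[apply(ds$expression, 1, max) > 0]]
dars      <- regions[regions$region_class == "DAR" & regions$lineage == "ect"]

zs <- zoneScan(deg, ds$expression[deg$gene_id, "ect"], dars, expressed,
               grid = c(20, 40, 80, 120, 160, 200) * 1000)
zs
#> ZoneScan over 6 vicinities [20, 200] kB
#>   Z* = 80 kB (r = 0.957, p = 0.00267, 6 frequency groups)

links <- linkRegions(deg, dars, ds$tads, zStar(zs))
linkSummary(links)
#> $n_links 647  $n_genes 29  $median_abs_distance 40133  $frac_beyond 0
```

Reading: 29 of the 30 planted ectoderm DEGs are recovered (the SEG/DEG
counts match the planted fractions), the accessibility caller recovers the
planted differential windows, the scan finds the strongest
expression-accessibility coupling at an 80-kB vicinity — the grid point
just inside the 100-kB zone the generator used — and the TAD-constrained
catalogue links 647 candidate enhancers to the 29 ectoderm genes, none
farther than 100 kB.

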