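---
title: "Separating developmental and housekeeping regulatory programs with chromlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating developmental and housekeeping regulatory programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

chromlink analyses three-lineage pseudo-bulk multi-omic data — a gene
expression table (log2 RPKM per germ layer), per-window GpC accessibility
and CpG methylation counts, TAD intervals, and externally derived enriched
TF-motif lists — under one organising statistic: the Berger-Parker
dominance index, Dom = max(x_i)/sum(x_i) of the three per-lineage values.
Dom ranges from 1/3 (perfectly even) to 1 (single-lineage), and is
scale-free, which makes the same thresholds usable across data types:
Dom >= 0.6 calls strong single-lineage dominance, Dom <= 0.34 calls
near-even behaviour.

Applied to expression it separates lineage-specific genes (DEGs, a proxy
for developmental regulators) from similarly expressed genes (SEGs, a proxy
for housekeeping genes). Applied to window-level accessibility it calls
differentially vs similarly accessible regions (DARs / SARs); applied to
hypomethylation it calls DhMRs / ShMRs. The downstream claims the package
quantifies are: DEGs are genomically isolated while SEGs cluster; DARs
spread over ~100 kB around DEG promoters while SARs sit at SEG promoters;
expression couples to distal open-chromatin abundance for DEGs but not
SEGs; and the two programs use distinguishable TF-motif repertoires.

### Assumptions

* Expression triples are comparable across lineages (same normalisation);
  dominance is computed on the linear scale.
* Window counts are pseudo-bulk aggregates; per-window levels are binomial
  fractions of informative dinucleotides.
* TADs are a trusted input annotation; a regulatory link never crosses a
  TAD boundary.
* Motif lists come from upstream enrichment tools; only their ranked
  membership and consensus sequences are consumed here.

## Key parameters (defaults and why)

| parameter | default | role |
|---|---|---|
| `dHigh`, `dLow` | 0.6, 0.34 | dominance thresholds for differential / similar calls, on all data types; 0.34 marks "almost even" (even = 0.33) |
| `minExpr` | 2 log2 RPKM | DEG floor: the dominant lineage must actually express the gene (also the conditioned permutation-pool floor) |
| `segMinExpr` | 0 log2 RPKM | SEG floor: housekeeping genes are expressed everywhere |
| QC | reads > 25, reads/dinucleotides > 2, cv(coverage) < 1, cv(dinucleotides) < 3 | drops low-confidence and unbalanced windows before calling |
| `haCut` | 0.35 | SAR split into highly vs lowly accessible |
| `shmrCeiling` | 0.5 | ShMRs must be similarly *low* methylated |
| window widths | 100 bp (accessibility), 500 bp (methylation) | genome-tiled from position 0 of each chromosome |
| vicinity grid | 20–400 kB | zone-of-influence scan; extendable to 1 Mb via `chromlinkConfig()` |
| `digits` | 2 | rounding of the normalised frequency before grouping in the CAC |
| cluster vicinity | 10 kB | region-to-region clustering statistic |
| permutations | 1000 | p = (k+1)/(n+1), reported as 1/n when k = 0 (0/1000 prints as 0.001) |

## Numerical and design choices

**Linearisation.** Expression arrives as log2 RPKM (negative values are
meaningful), but ratios of log-scale values are meaningless near zero, so
dominance is always computed on 2^GE. This reproduces Dom = 1/3 for an even
triple exactly and keeps the index scale-free. Both dominance bounds are
inclusive so that the worked boundary values (linear (3,1,1) -> 0.6;
(34,33,33) -> 0.34) classify.

**Coordinates.** Files on disk use 0-based half-open BED conventions; in
memory everything is a `GRanges` (1-based closed). Conversion happens
exactly once, in the readers/writers. A region's centre is
start + floor(width/2), i.e. the natural midpoint of the half-open
interval; a TSS on a TAD's end coordinate belongs to the following TAD.

**QC balance inequalities.** The coverage/GC balance rules are stated as
"variability less than one standard deviation over mean". Taken literally
as |max|d_ij| − mean| < sd they reject a perfectly balanced window (|0 −
mean| < 0 is false), so the default `"cv"` variant reads them as a
coefficient-of-variation bound (sd/mean < 1 for coverage, < 3 for
dinucleotide counts, sample sd); the `"literal"` variant is retained for
auditability. With three replicate values a cv bound of 1 only rejects
imbalances of roughly five-fold and above; the filter is a coarse guard,
not a calibrated test.

**Methylation polarity.** The differential-methylation caller's dominance
is computed on h = 1 − M by default, so the dominant lineage is the most
*hypo*methylated one — matching the interpretation of these regions as
lineage-specific active elements. The `"literal"` polarity (dominance on M
itself, labelling the most methylated lineage) is selectable. The ShMR
"similarly low" requirement uses a mean-methylation ceiling of 0.5 under
either polarity.

**No window merging.** Each qualifying window is one region; adjacent
qualifying windows are not merged, so region counts are window-resolution.

**CAC grouping.** The correlation is computed over points (f, mean GE of
the genes sharing f), with f rounded to two decimals; at least three
distinct groups are required for a reported coefficient. A
group-size-weighted variant was considered and rejected: weighting rewards
the coarse groupings that small vicinities produce and inverts the
vicinity preference of the scan.

**Z\* eligibility.** Correlations estimated from a handful of frequency
groups are noisy, and the argmax over the grid would otherwise be won
spuriously by small vicinities where counts are coarse. A grid point
therefore competes for Z\* only when it resolves at least 20% of the gene
set (never fewer than 10 groups) into distinct frequencies — the package's
reading of scanning only vicinities that keep a workable region density.
Ties break toward the smaller vicinity (the more local explanation). When
no grid point reaches the bar, eligibility falls back to any defined
coefficient rather than failing.

**Linked criterion.** Results-style "R > 0.7" and methods-style
"R^2 > 0.7" are both obtainable from the returned curve; the package
reports r and p and leaves the cut to the caller.

**Quartile ranks.** A list of n motifs is split at ranks ceiling(n/4),
ceiling(n/2), ceiling(3n/4) (a 5-motif list splits 2,1,1,1); absent motifs
score 0, and the RMSE between two repertoire vectors is taken over the full
shared union, zeros included. IUPAC degenerate consensus symbols contribute
fractional nucleotide counts (R = half A, half G) to Px/Pxy and the
dinucleotide entropy. GC strata for the rank permutation are quartiles of
union GC content.

## The synthetic data generator

`generateDataset(simulationSpec())` emulates the study conditions at desk
scale: three chromosomes of 24 Mb, 300 genes of which 30% are DEGs (split
across lineages), 30% SEGs, the rest background, plus 20 silent TF genes.

* **Expression.** DEGs: base log2 RPKM ~ N(2, 1), non-dominant lineages
  jittered with sd 0.5, dominant lineage boosted 8-fold (+3 log2) — Monte
  Carlo puts P(Dom >= 0.6) at ~0.99 under these values. SEGs: a shared
  gene effect N(5, 1.5) with per-lineage jitter sd 0.01 in log2, the
  evenness the Dom <= 0.34 definition requires (P ~ 0.999). Background: a
  lineage-correlated baseline N(4, 2.5) with jitter sd 0.4, giving a
  false-DEG rate ~0.1% and false-SEG rate ~0.7%.
* **Architecture.** Alternating domains: each DEG sits alone in a ~600-kB
  TAD, SEGs come in 5-gene clusters (2–10 kB inter-TSS gaps) inside
  ~300-kB TADs; domains are separated by 20–60 kB gaps. This realises the
  isolated-DEG / clustered-SEG contrast by construction.
* **Chromatin.** Each DEG receives Poisson(5 × expression decile) distal
  open windows uniformly within ±100 kB of its TSS (dominant-lineage level
  0.85 vs 0.05); each SEG gets two proximal open windows within ±2 kB at an
  even level of 0.55; background windows are even and low. Counts: reads ~
  Poisson(50), GpC dinucleotides ~ Poisson(15) per 100-bp window, CpGs ~
  Poisson(30) per 500-bp window, methylated counts binomial at the target
  level. Methylation is anti-correlated with accessibility: 20% of planted
  DARs carry a matching hypomethylated 500-bp window, and every SEG
  promoter is evenly hypomethylated.
* **Motifs.** Two grammars (developmental / housekeeping) with a shared
  core of 80% within a grammar and 20% between grammars; housekeeping
  consensi are GC-rich at rate 0.9; 25% of motifs point at silent origin
  genes so the expression filter's drop rate is known.

What the generator does **not** model: binomial evenness noise at
realistic dinucleotide counts means that only a minority of the planted
even-level windows are actually *called* SAR/ShMR (the three levels must
agree to ~2% for Dom <= 0.34); real pseudo-bulk data with deeper
aggregate counts are less affected. It also has no sequence content (no
FASTA), no replicate/cell-level structure, no distance-decaying enhancer
placement, and no correlated noise between data layers beyond the planted
anti-correlation — so passing tests demonstrate the machinery recovers
planted structure under idealised noise, not performance on real data.

The zone-scan calibration scenario (`simulateLinkingScenario()`) places
300 dominant genes with jittered regular spacing on one 50-Mb chromosome.
Isolation matters: with uniformly random gene placement, neighbouring
genes' region clouds overlap the vicinity windows and attenuate the CAC
(measured max r drops from ~0.92 to ~0.70); regular spacing is also the
truthful rendering of the isolated-DEG architecture.

## Calibration of the permutation tests

All five permutation tests (dominance threshold, set-enrichment overlap,
TAD co-occurrence, region clustering, GC-stratified repertoire) are
checked for uniform p-values under their own nulls (1000 replicates,
Kolmogorov-Smirnov). The statistics of the overlap-, count- and
fraction-valued tests are discrete, so their p-values are conservative by
construction; the calibration scenarios are sized so that the statistic's
support is fine enough for the KS check to pass (e.g. 1600 TADs / 4800
genes for the co-occurrence null). Test-suite problem sizes (200–4800
genes, 99–199 permutations per replicate) were chosen as the smallest
instances at which these distributional checks are stable.

## Known limitations

* SAR/ShMR recall on shallow synthetic counts is low (see above); DAR
  recall is the calibrated quantity (>= 0.9 at default coverage).
* The MAD-score DEG strategy uses a robust z-score of pairwise log-ratios
  as its outlier rule; the original score's exact definition is not
  specified by its citation, so this is a stated stand-in, kept separate
  from the dominance labels and compared to them by Jaccard agreement.
* `cgRichPromoter()` classifies CpG-island-like promoters with
  Gardiner-Garden-style cutoffs (GC > 0.5, CpG O/E > 0.6 over >= 200 bp)
  on a [-1000, +500] window; both are conventions, configurable.
* Zone scans pool chromosomes by default; per-chromosome scans are a
  subsetting of the inputs, and the grid stops at 400 kB unless extended.
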