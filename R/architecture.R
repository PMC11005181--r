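#' Distance to the nearest expressed neighbouring TSS
#'
#' Orders the retained genes by TSS within each chromosome and reports, for
#' every retained gene, the smaller of the distances to the adjacent
#' retained TSSs. The expression filter applies to the neighbour set as well
#' as to the focal gene, so raising the threshold can only increase a
#' retained gene's distance. A chromosome's only retained gene gets `NA`.
#'
#' @param genes `GRanges` gene annotation (width-1 TSS).
#' @param expr optional log2 RPKM matrix; when `NULL` all annotated genes
#'   are retained (the "all genes" mode).
#' @param threshold log2 RPKM expression threshold; a gene is retained when
#'   its expression exceeds it.
#' @param lineage `"any"` (default: max across lineages) or a lineage code.
#' @return data.frame with `gene_id`, `chrom`, `tss`, `d` (bp) and
#'   `threshold`.
#' @export
nearestExpressedDistance <- function(genes, expr = NULL, threshold = -Inf,
                                     lineage = c("any", .LINEAGES)) {
    lineage <- match.arg(lineage)
    keep <- rep(TRUE, length(genes))
    if (!is.null(expr)) {
        expr <- .checkExpr(expr)
        expr[is.na(expr)] <- -Inf
        level <- if (lineage == "any") apply(expr, 1L, max)
                 else expr[, lineage]
        keep <- genes$gene_id %in% rownames(expr)[level > threshold]
    }
    g <- genes[keep]
    if (length(g) == 0L) {
        warning("no genes retained at threshold ", threshold)
        return(data.frame(gene_id = character(), chrom = character(),
                          tss = integer(), d = numeric(),
                          threshold = numeric()))
    }
    res <- lapply(split(g, as.character(seqnames(g))), function(gc) {
        o <- order(start(gc))
        gc <- gc[o]
        tss <- start(gc)
        n <- length(tss)
        d <- rep(NA_real_, n)
        if (n >= 2L) {
            gaps <- diff(tss)
            left <- c(Inf, gaps)
            right <- c(gaps, Inf)
            d <- pmin(left, right)
        }
        data.frame(gene_id = gc$gene_id,
                   chrom = as.character(seqnames(gc)),
                   tss = tss - 1L, d = d)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out$threshold <- threshold
    out
}

#' Compare nearest-neighbour distance distributions (Mann-Whitney)
#'
#' @param dDeg,dSeg numeric distance vectors (NAs dropped).
#' @return list with `statistic`, `p.value` and the two `medians`.
#' @export
compareDistances <- function(dDeg, dSeg) {
    dDeg <- dDeg[!is.na(dDeg)]
    dSeg <- dSeg[!is.na(dSeg)]
    if (!length(dDeg) || !length(dSeg))
        stop("both distance samples must be non-empty")
    if (length(unique(c(dDeg, dSeg))) == 1L) {
        warning("all distances tied; p = 1")
        return(list(statistic = NA_real_, p.value = 1,
                    medians = c(deg = stats::median(dDeg),
                                seg = stats::median(dSeg))))
    }
    exact <- length(dDeg) < 50 && length(dSeg) < 50 &&
        !anyDuplicated(c(dDeg, dSeg))
    wt <- stats::wilcox.test(dDeg, dSeg, exact = exact)
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         medians = c(deg = stats::median(dDeg), seg = stats::median(dSeg)))
}

# TSS-in-TAD assignment under the half-open convention: a TSS exactly on a
# TAD's end coordinate belongs to the following TAD, not this one.
.assignTads <- function(genes, tads) {
    hits <- findOverlaps(genes, tads, ignore.strand = TRUE)
    idx <- rep(NA_integer_, length(genes))
    idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    idx
}

#' Per-TAD gene content and density
#'
#' Genes are assigned to the TAD whose half-open interval contains their
#' TSS; genes outside all TADs are counted as unassigned. Density is genes
#' per 100 kB: n_genes * 100000 / TAD length.
#'
#' @param tads `GRanges` with `tad_id`.
#' @param genes `GRanges` annotation whose `class_label` column carries the
#'   DEG/SEG classification.
#' @return `DataFrame` with `tad_id`, `length`, `n_genes`, `n_DEG`,
#'   `n_SEG`, `density` and `content`
#'   (DEG_only / SEG_only / mixed / other / empty); the number of unassigned
#'   genes is stored in `metadata()$n_unassigned`.
#' @export
tadSummaries <- function(tads, genes) {
    idx <- .assignTads(genes, tads)
    isDeg <- startsWith(genes$class_label %|NA|% "", "DEG")
    isSeg <- (genes$class_label %|NA|% "") == "SEG"
    cnt <- function(sel) tabulate(idx[sel & !is.na(idx)], length(tads))
    nGenes <- tabulate(idx[!is.na(idx)], length(tads))
    nDeg <- cnt(isDeg)
    nSeg <- cnt(isSeg)
    content <- rep("other", length(tads))
    content[nGenes == 0] <- "empty"
    content[nDeg > 0 & nSeg == 0] <- "DEG_only"
    content[nSeg > 0 & nDeg == 0] <- "SEG_only"
    content[nDeg > 0 & nSeg > 0] <- "mixed"
    out <- DataFrame(tad_id = tads$tad_id, length = width(tads),
                     n_genes = nGenes, n_DEG = nDeg, n_SEG = nSeg,
                     density = nGenes * 1e5 / width(tads),
                     content = content)
    metadata(out)$n_unassigned <- sum(is.na(idx))
    out
}

#' Permutation test for DEG/SEG co-occurrence within TADs
#'
#' The observed statistic is the number of TADs containing at least one DEG
#' and at least one SEG. The null shuffles the class labels over the fixed
#' gene positions; spatial segregation of the two programs shows up as
#' fewer mixed TADs than the shuffled null (`alternative = "less"`,
#' the default).
#'
#' @param tads `GRanges` with `tad_id`.
#' @param genes `GRanges` gene annotation.
#' @param degIds,segIds gene_id character vectors carrying the labels.
#' @param nPerm,seed permutation count and RNG seed.
#' @param alternative `"less"` (depletion of mixed TADs) or `"greater"`.
#' @return list with `nMixed`, `counts` (DEG-only/SEG-only/mixed TAD
#'   tallies) and `report` (a [PermutationReport-class]; p-value `NA` with a
#'   warning when no TAD holds two or more labelled genes).
#' @export
tadCooccurrenceTest <- function(tads, genes, degIds, segIds, nPerm = 1000,
                                seed = 1,
                                alternative = c("less", "greater")) {
    alternative <- match.arg(alternative)
    nT <- length(tads)
    idx <- .assignTads(genes, tads)
    ids <- genes$gene_id
    lab <- rep(0L, length(idx))          # 1 = DEG, 2 = SEG
    lab[ids %in% degIds] <- 1L
    lab[ids %in% segIds] <- 2L
    inTad <- !is.na(idx)
    idxT <- idx[inTad]
    labT <- lab[inTad]
    nMixedOf <- function(labT) {
        d <- tabulate(idxT[labT == 1L], nT) > 0
        s <- tabulate(idxT[labT == 2L], nT) > 0
        c(deg_only = sum(d & !s), seg_only = sum(s & !d), mixed = sum(d & s))
    }
    obs <- nMixedOf(labT)
    labelledPerTad <- tabulate(idxT[labT > 0L], nT)
    if (!any(labelledPerTad >= 2L)) {
        warning("no TAD contains two or more labelled genes; ",
                "co-occurrence test undefined")
        rep <- PermutationReport("mixed TADs", obs["mixed"], nPerm, 0L, seed)
        rep@pValue <- NA_real_
        return(list(nMixed = unname(obs["mixed"]), counts = obs,
                    report = rep))
    }
    # labels are shuffled over all gene positions; only the in-TAD part of
    # the shuffled vector matters for the statistic
    set.seed(seed)
    null <- vapply(seq_len(nPerm),
                   function(i) nMixedOf(sample(lab)[inTad])["mixed"],
                   numeric(1))
    k <- if (alternative == "less") sum(null <= obs["mixed"])
         else sum(null >= obs["mixed"])
    list(nMixed = unname(obs["mixed"]), counts = obs,
         report = PermutationReport("mixed TADs", obs["mixed"], nPerm, k,
                                    seed))
}

#' Classify promoters as CG-rich and test class association
#'
#' The promoter is the strand-aware window `window` around the TSS. A
#' promoter is CG-rich when its GC fraction exceeds `gcMin` and its CpG
#' observed/expected ratio exceeds `oeMin` over at least `minWidth` bp
#' (Gardiner-Garden-style criteria). Either promoter sequences or
#' precomputed per-promoter statistics must be supplied. The association
#' between gene class (SEG vs DEG) and CG-richness is tested with a
#' one-tailed Fisher exact test.
#'
#' @param genes `GRanges` annotation with `class_label`.
#' @param sequences optional named `DNAStringSet` (or character vector) of
#'   promoter sequences keyed by gene_id.
#' @param promoterStats optional data.frame with `gene_id`, `gc`, `cpg_oe`,
#'   `width` when sequences are not available.
#' @param window promoter window relative to the TSS, strand-aware
#'   (default -1000..+500).
#' @param gcMin,oeMin,minWidth CG-richness cutoffs.
#' @return list with `perGene` (gene_id, cg_rich), the 2x2 `table` and the
#'   `fisher` htest (alternative "greater" for SEG enrichment in CG-rich).
#' @export
cgRichPromoter <- function(genes, sequences = NULL, promoterStats = NULL,
                           window = c(-1000, 500), gcMin = 0.5, oeMin = 0.6,
                           minWidth = 200) {
    if (is.null(sequences) && is.null(promoterStats))
        stop("need promoter sequences or precomputed promoter statistics")
    if (!is.null(sequences)) {
        seqs <- Biostrings::DNAStringSet(sequences)
        L <- Biostrings::width(seqs)
        mono <- Biostrings::letterFrequency(seqs, c("C", "G"))
        cg <- Biostrings::vcountPattern("CG", seqs)
        gc <- rowSums(mono) / L
        oe <- ifelse(mono[, "C"] > 0 & mono[, "G"] > 0,
                     cg * L / (mono[, "C"] * mono[, "G"]), 0)
        promoterStats <- data.frame(gene_id = names(seqs), gc = gc,
                                    cpg_oe = oe, width = L)
    }
    st <- promoterStats[match(genes$gene_id, promoterStats$gene_id), ]
    rich <- !is.na(st$gc) & st$gc > gcMin & st$cpg_oe > oeMin &
        st$width >= minWidth
    cls <- genes$class_label %|NA|% "unclassified"
    isSeg <- cls == "SEG"
    isDeg <- startsWith(cls, "DEG")
    tab <- matrix(c(sum(isSeg & rich), sum(isSeg & !rich),
                    sum(isDeg & rich), sum(isDeg & !rich)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(class = c("SEG", "DEG"),
                                  cg_rich = c("yes", "no")))
    fisher <- if (all(rowSums(tab) > 0))
        stats::fisher.test(tab, alternative = "greater") else NULL
    list(perGene = data.frame(gene_id = genes$gene_id, cg_rich = rich),
         table = tab, fisher = fisher)
}
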