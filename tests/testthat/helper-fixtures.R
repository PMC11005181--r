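# in-code fixtures shared across test files

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
    library(IRanges)
})

# width-1 TSS annotation from parallel vectors
makeGenes <- function(chrom, tss, strand = "+", ids = NULL,
                      class_label = "unclassified") {
    GenomicRanges::GRanges(
        chrom, IRanges::IRanges(tss + 1L, width = 1L), strand = strand,
        gene_id = if (is.null(ids)) sprintf("g%03d", seq_along(tss)) else ids,
        class_label = class_label)
}

makeTads <- function(chrom, start, end, ids = NULL) {
    GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start + 1L, end),
        tad_id = if (is.null(ids)) sprintf("tad%02d", seq_along(start))
                 else ids)
}

# expression matrix from a list of per-gene linear triples (log2-ised)
exprFromLinear <- function(..., ids = NULL) {
    rows <- list(...)
    m <- log2(do.call(rbind, rows))
    rownames(m) <- if (is.null(ids)) sprintf("g%03d", seq_along(rows))
                   else ids
    colnames(m) <- c("ect", "end", "mes")
    m
}

# SignalWindows with given per-lineage target levels and deterministic
# counts (dinucTotal = denom everywhere, meth = round(level * denom))
windowsFromLevels <- function(levels, chrom = "chr1", width = 100,
                              reads = 30, denom = 100) {
    levels <- matrix(levels, ncol = 3, byrow = TRUE)
    n <- nrow(levels)
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(seq_len(n) * width * 2 + 1, width = width))
    SignalWindows(gr,
                  reads = matrix(reads, n, 3),
                  dinucTotal = matrix(denom, n, 3),
                  dinucMeth = round(levels * denom))
}

# brute-force oracles -------------------------------------------------

# nearest retained TSS distance by all-pairs search
oracleNearest <- function(chrom, tss) {
    vapply(seq_along(tss), function(i) {
        same <- which(chrom == chrom[i])
        same <- setdiff(same, i)
        if (!length(same)) return(NA_real_)
        min(abs(tss[same] - tss[i]))
    }, numeric(1))
}

# TAD containment count by explicit interval check (0-based half-open)
oracleTadCounts <- function(tadStart0, tadEnd0, tadChrom, tss0, geneChrom) {
    vapply(seq_along(tadStart0), function(t) {
        sum(geneChrom == tadChrom[t] & tss0 >= tadStart0[t] &
                tss0 < tadEnd0[t])
    }, integer(1))
}

# double-loop link catalogue: both predicates applied literally
oracleLinks <- function(genes, regions, tads, zStar) {
    gTss <- GenomicRanges::start(genes)
    rCent <- GenomicRanges::start(regions) + floor(GenomicRanges::width(regions) / 2)
    inTad <- function(chrom, pos) {
        hit <- which(as.character(GenomicRanges::seqnames(tads)) == chrom &
                         GenomicRanges::start(tads) <= pos &
                         GenomicRanges::end(tads) >= pos)
        if (length(hit)) hit[1] else NA_integer_
    }
    out <- list()
    for (g in seq_along(genes)) {
        tg <- inTad(as.character(GenomicRanges::seqnames(genes))[g], gTss[g])
        if (is.na(tg)) next
        for (r in seq_along(regions)) {
            tr <- inTad(as.character(GenomicRanges::seqnames(regions))[r],
                        rCent[r])
            if (is.na(tr) || tr != tg) next
            if (abs(rCent[r] - gTss[g]) <= zStar)
                out[[length(out) + 1L]] <- data.frame(
                    gene = genes$gene_id[g], region_start =
                        GenomicRanges::start(regions)[r],
                    distance = (rCent[r] - gTss[g]) *
                        (if (as.character(GenomicRanges::strand(genes))[g] ==
                             "-") -1 else 1))
        }
    }
    if (!length(out)) return(data.frame(gene = character(),
                                        region_start = integer(),
                                        distance = numeric()))
    df <- do.call(rbind, out)
    df[order(df$region_start, df$gene), ]
}

# per-gene accessibility-index tally, direct per the definition
oracleProfile <- function(centres, tss, expressed, V, bin, strandSign) {
    nBins <- 2 * V / bin
    tot <- numeric(nBins)
    used <- 0L
    for (i in seq_along(tss)) {
        ng <- sum(expressed >= tss[i] - V & expressed <= tss[i] + V)
        if (ng == 0) next
        used <- used + 1L
        rel <- (centres - tss[i]) * strandSign[i]
        rel <- rel[rel >= -V & rel < V]
        for (r in rel) {
            j <- floor((r + V) / bin) + 1
            tot[j] <- tot[j] + 1 / ng
        }
    }
    tot / used
}
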