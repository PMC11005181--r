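#' Compute per-lineage signal levels for windows
#'
#' The level of a window in a lineage is the fraction of methylated
#' informative dinucleotides, dinucMeth / dinucTotal (GpC for NOMe-seq
#' accessibility, where methylated means accessible; CpG for endogenous
#' methylation). Windows with a zero dinucleotide total in any lineage have
#' no defined level and are dropped, with the count logged.
#'
#' @param sw a [SignalWindows-class].
#' @return the object restricted to windows with defined levels in all
#'   three lineages, with a `level` assay added.
#' @export
windowLevels <- function(sw) {
    tot <- assay(sw, "dinucTotal")
    ok <- rowSums(tot > 0) == 3L
    if (any(!ok))
        message("windowLevels: dropped ", sum(!ok),
                " windows with no informative dinucleotides")
    sw <- sw[ok, ]
    lev <- assay(sw, "dinucMeth") / assay(sw, "dinucTotal")
    assays(sw)$level <- lev
    sw
}

#' Quality-control filter for signal windows
#'
#' Three filters applied in sequence, each per window across the three
#' lineages: (1) coverage: reads > `minReads` and reads / dinucTotal >
#' `readsPerDinuc` in every lineage; (2) coverage balance; (3) dinucleotide
#' count balance. The default `"cv"` variant reads "variability less than
#' one standard deviation over mean" as a coefficient-of-variation bound
#' (sd/mean < `covCvMax` for coverage, < `gcCvMax` for dinucleotide counts;
#' sample sd, n - 1). The `"literal"` variant applies the printed
#' inequalities |max|d_ij| - mean| < sd and |max|dif_numGC_ij| - mean| <
#' 3 sd, retained for auditability although they reject perfectly balanced
#' windows (|0 - mean| < sd fails whenever sd = 0 and coverage > 0).
#'
#' @param sw a [SignalWindows-class].
#' @param variant `"cv"` (default) or `"literal"`.
#' @param minReads,readsPerDinuc coverage filter cutoffs (defaults 25 and 2).
#' @param covCvMax,gcCvMax cv-variant balance bounds (defaults 1 and 3).
#' @return list with `windows` (the retained [SignalWindows-class]) and
#'   `report` (counts in/out per filter and the variant used).
#' @export
qcFilter <- function(sw, variant = c("cv", "literal"), minReads = 25,
                     readsPerDinuc = 2, covCvMax = 1, gcCvMax = 3) {
    variant <- match.arg(variant)
    reads <- assay(sw, "reads")
    tot <- assay(sw, "dinucTotal")
    if (any(reads < 0) || any(tot < 0)) stop("negative counts")
    pass1 <- rowSums(reads > minReads) == 3L &
        rowSums(tot > 0) == 3L & rowSums(reads / pmax(tot, 1) >
                                             readsPerDinuc) == 3L
    rowSd <- function(m) {
        mu <- rowMeans(m)
        sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
    }
    balance <- function(m, k) {
        mu <- rowMeans(m)
        s <- rowSd(m)
        if (variant == "cv") {
            s / mu < k
        } else {
            spread <- apply(m, 1L, function(v) max(v) - min(v)) # max |d_ij|
            abs(spread - mu) < k * s
        }
    }
    pass2 <- pass1 & balance(reads, if (variant == "cv") covCvMax else 1)
    pass3 <- pass2 & balance(tot, if (variant == "cv") gcCvMax else 3)
    report <- list(n_windows_in = nrow(sw),
                   n_pass_coverage = sum(pass1),
                   n_pass_coverage_balance = sum(pass2),
                   n_pass_gc_balance = sum(pass3),
                   variant = variant)
    message(sprintf(
        "qcFilter(%s): %d -> %d (coverage) -> %d (cov balance) -> %d (GC balance)",
        variant, report$n_windows_in, report$n_pass_coverage,
        report$n_pass_coverage_balance, report$n_pass_gc_balance))
    list(windows = sw[pass3, ], report = report)
}

# shared caller: dominance on a level matrix with high/low thresholds
.callByDominance <- function(gr, levels, dHigh, dLow) {
    tot <- rowSums(levels)
    keep <- tot > 0 & !apply(levels, 1L, anyNA)
    list(gr = gr[keep], levels = levels[keep, , drop = FALSE],
         dom = dominanceIndex(levels[keep, , drop = FALSE]),
         skipped = sum(!keep))
}

#' Call differentially and similarly accessible regions (DARs / SARs)
#'
#' The accessibility dominance Da = max(A_i) / sum(A_i) is computed on the
#' three per-lineage levels of every QC-passed window. A window is a DAR
#' for the argmax lineage when Da >= `dHigh`; a SAR when Da <= `dLow`,
#' subdivided into highly accessible (SAR_HA, mean level > `haCut`) and low
#' accessible (SAR_LA). Each qualifying window is one region; adjacent
#' windows are not merged, so counts are window-resolution.
#'
#' @param sw a levelled [SignalWindows-class] (see [windowLevels()]).
#' @param dHigh,dLow dominance thresholds (defaults 0.6 / 0.34).
#' @param haCut HA/LA mean-accessibility split (default 0.35).
#' @return `GRanges` with `region_class` (DAR/SAR_HA/SAR_LA), `lineage`
#'   (argmax lineage for DARs, "all" for SARs), `dominance` and
#'   `mean_level`.
#' @export
callAccessibilityRegions <- function(sw, dHigh = 0.6, dLow = 0.34,
                                     haCut = 0.35) {
    if (!"level" %in% names(assays(sw))) sw <- windowLevels(sw)
    cc <- .callByDominance(rowRanges(sw), assay(sw, "level"), dHigh, dLow)
    if (cc$skipped)
        message("callAccessibilityRegions: skipped ", cc$skipped,
                " all-zero windows")
    da <- cc$dom
    mlev <- rowMeans(cc$levels)
    isDar <- da >= dHigh
    isSar <- da <= dLow
    keep <- isDar | isSar
    out <- cc$gr[keep]
    cls <- ifelse(isDar[keep], "DAR",
                  ifelse(mlev[keep] > haCut, "SAR_HA", "SAR_LA"))
    out$region_class <- cls
    out$lineage <- ifelse(isDar[keep],
                          .rowArgmaxLineage(cc$levels)[keep], "all")
    out$dominance <- da[keep]
    out$mean_level <- mlev[keep]
    out
}

#' Call differentially and similarly hypomethylated regions (DhMRs / ShMRs)
#'
#' Methylation windows (500 bp) carry per-lineage CpG methylation fractions
#' M_i. Under the default `"hypo"` polarity the dominance index is computed
#' on h_i = 1 - M_i, so the dominant lineage is the most hypomethylated
#' one, matching the regions' description as lineage-specific
#' hypomethylated elements. The `"literal"` polarity applies the dominance
#' to M_i unchanged (so it labels the most methylated lineage). A window is
#' a DhMR for the dominant lineage at Dom >= `dHigh`; a ShMR at
#' Dom <= `dLow` provided the mean methylation is below `shmrCeiling`
#' ("similarly low" methylation; the ceiling applies under both polarities).
#'
#' @param sw a levelled 500-bp [SignalWindows-class] of CpG counts.
#' @param polarity `"hypo"` (default) or `"literal"`.
#' @param dHigh,dLow dominance thresholds.
#' @param shmrCeiling maximum mean methylation for a ShMR (default 0.5).
#' @return `GRanges` with `region_class` (DhMR/ShMR), `lineage`,
#'   `dominance` and `mean_level` (mean methylation).
#' @export
callMethylationRegions <- function(sw, polarity = c("hypo", "literal"),
                                   dHigh = 0.6, dLow = 0.34,
                                   shmrCeiling = 0.5) {
    polarity <- match.arg(polarity)
    if (!"level" %in% names(assays(sw))) sw <- windowLevels(sw)
    m <- assay(sw, "level")
    h <- if (polarity == "hypo") 1 - m else m
    cc <- .callByDominance(rowRanges(sw), h, dHigh, dLow)
    keepM <- m[rowSums(h) > 0 & !apply(h, 1L, anyNA), , drop = FALSE]
    dom <- cc$dom
    meanM <- rowMeans(keepM)
    isD <- dom >= dHigh
    isS <- dom <= dLow & meanM < shmrCeiling
    keep <- isD | isS
    out <- cc$gr[keep]
    out$region_class <- ifelse(isD[keep], "DhMR", "ShMR")
    out$lineage <- ifelse(isD[keep], .rowArgmaxLineage(cc$levels)[keep],
                          "all")
    out$dominance <- dom[keep]
    out$mean_level <- meanM[keep]
    out
}

#' Fraction of regions with a companion region nearby, with shift null
#'
#' For every region in `setA`, checks whether at least one centre of `setB`
#' lies within `vicinity` bp of its centre (midpoint). Also reports the
#' base-pair Jaccard index of the two interval sets and a permutation test
#' in which `setB` is circularly shifted by a uniform offset within each
#' chromosome.
#'
#' @param setA,setB `GRanges` region sets sharing chromosome naming.
#' @param vicinity half-width around the centre (default 10,000 bp).
#' @param nPerm,seed permutation count and RNG seed.
#' @param chromLengths named vector of chromosome lengths for the shift
#'   null; taken from `seqlengths(setB)` or the maximum observed coordinate
#'   when absent.
#' @param jaccard compute the base-pair Jaccard index of the two interval
#'   sets (default `TRUE`; skip for speed in repeated calls).
#' @return list with `fraction`, `jaccard` and `report`
#'   (a [PermutationReport-class]; alternative: observed fraction larger
#'   than the shifted null).
#' @export
clusterFraction <- function(setA, setB, vicinity = 10000, nPerm = 1000,
                            seed = 1, chromLengths = NULL, jaccard = TRUE) {
    if (length(setA) == 0L || length(setB) == 0L) {
        warning("empty region set; fraction = 0")
        return(list(fraction = 0, jaccard = 0, report = NULL))
    }
    centA <- split(.centres(setA),
                   as.character(seqnames(setA)))
    centB <- split(.centres(setB),
                   as.character(seqnames(setB)))
    if (is.null(chromLengths)) {
        sl <- seqlengths(setB)
        chromLengths <- if (all(!is.na(sl))) sl
            else vapply(unique(c(names(centA), names(centB))), function(ch)
                max(c(end(setA[seqnames(setA) == ch]),
                      end(setB[seqnames(setB) == ch]), 1)) + vicinity,
                numeric(1))
    }
    fracNear <- function(centB) {
        hits <- 0L
        for (ch in names(centA)) {
            b <- centB[[ch]]
            if (is.null(b) || !length(b)) next
            b <- sort(b)
            a <- centA[[ch]]
            hits <- hits +
                sum(findInterval(a + vicinity, b) -
                        findInterval(a - vicinity - 1, b) > 0)
        }
        hits / length(setA)
    }
    obs <- fracNear(centB)
    jac <- NA_real_
    if (jaccard) {
        ia <- GenomicRanges::reduce(setA, ignore.strand = TRUE)
        ib <- GenomicRanges::reduce(setB, ignore.strand = TRUE)
        inter <- sum(width(GenomicRanges::intersect(ia, ib,
                                                    ignore.strand = TRUE)))
        uni <- sum(width(GenomicRanges::union(ia, ib, ignore.strand = TRUE)))
        jac <- if (uni == 0) 0 else inter / uni
    }
    set.seed(seed)
    null <- vapply(seq_len(nPerm), function(i) {
        shifted <- lapply(names(centB), function(ch) {
            len <- chromLengths[[ch]]
            (centB[[ch]] + floor(stats::runif(1, 0, len))) %% len
        })
        names(shifted) <- names(centB)
        fracNear(shifted)
    }, numeric(1))
    list(fraction = obs, jaccard = jac,
         report = PermutationReport("clustered fraction", obs, nPerm,
                                    sum(null >= obs), seed))
}
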