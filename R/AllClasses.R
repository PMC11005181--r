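#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

# lineage codes used throughout; order is fixed and meaningful
.LINEAGES <- c("ect", "end", "mes")
.LINEAGE_NAMES <- c(ect = "ectoderm", end = "endoderm", mes = "mesoderm")
.DEG_CLASSES <- paste0("DEG_", .LINEAGE_NAMES)
.GENE_CLASSES <- c(.DEG_CLASSES, "SEG", "unclassified")

#' SignalWindows: per-window multi-lineage methylation-derived signal
#'
#' Container for fixed-width genomic windows carrying, for each of the three
#' germ-layer lineages, the read count, the number of informative
#' dinucleotides (GpC for NOMe-seq accessibility, CpG for endogenous
#' methylation) and the number of methylated dinucleotides. Extends
#' \linkS4class{RangedSummarizedExperiment} with assays \code{reads},
#' \code{dinucTotal} and \code{dinucMeth}; \code{\link{windowLevels}} adds
#' the derived \code{level} assay (methylated / total, in [0, 1]).
#'
#' @slot windowWidth integer(1), the fixed window width in bp (100 for
#'   accessibility, 500 for methylation).
#' @export
setClass("SignalWindows",
    contains = "RangedSummarizedExperiment",
    representation(windowWidth = "integer"))

setValidity("SignalWindows", function(object) {
    msg <- character()
    need <- c("reads", "dinucTotal", "dinucMeth")
    have <- names(assays(object))
    if (!all(need %in% have))
        msg <- c(msg, paste("missing assays:",
                            paste(setdiff(need, have), collapse = ", ")))
    if (!identical(colnames(object), .LINEAGES))
        msg <- c(msg, "columns must be exactly ect, end, mes")
    if (length(msg) == 0L) {
        tot <- assay(object, "dinucTotal")
        met <- assay(object, "dinucMeth")
        if (any(met < 0) || any(tot < 0) || any(assay(object, "reads") < 0))
            msg <- c(msg, "counts must be non-negative")
        if (any(met > tot))
            msg <- c(msg, "dinucMeth must not exceed dinucTotal")
        w <- width(rowRanges(object))
        if (length(w) && !all(w == object@windowWidth))
            msg <- c(msg, "all windows must have the configured width")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SignalWindows object
#'
#' @param windows `GRanges` of equal-width, non-overlapping windows.
#' @param reads,dinucTotal,dinucMeth numeric matrices (windows x 3 lineages,
#'   columns ect/end/mes) of read counts, informative dinucleotide counts
#'   and methylated dinucleotide counts.
#' @return A [SignalWindows-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), width = 100))
#' m <- function(...) matrix(c(...), nrow = 2, dimnames = list(NULL, c("ect", "end", "mes")))
#' sw <- SignalWindows(gr, m(30, 30, 30, 30, 30, 30), m(10, 10, 10, 10, 10, 10),
#'                     m(5, 5, 5, 5, 5, 5))
#' @export
SignalWindows <- function(windows, reads, dinucTotal, dinucMeth) {
    fix <- function(m) {
        m <- as.matrix(m)
        colnames(m) <- .LINEAGES
        m
    }
    w <- unique(width(windows))
    if (length(w) > 1L)
        stop("windows must share a single fixed width, got: ",
             paste(w, collapse = ", "))
    new("SignalWindows",
        SummarizedExperiment(
            assays = list(reads = fix(reads), dinucTotal = fix(dinucTotal),
                          dinucMeth = fix(dinucMeth)),
            rowRanges = windows),
        windowWidth = as.integer(if (length(w)) w else 0L))
}

#' @describeIn SignalWindows-class fixed window width (bp)
#' @param x a `SignalWindows` object
#' @export
windowWidth <- function(x) x@windowWidth

setMethod("show", "SignalWindows", function(object) {
    cat(sprintf("SignalWindows: %d windows of %d bp, lineages %s\n",
                nrow(object), object@windowWidth,
                paste(colnames(object), collapse = "/")))
    if ("level" %in% names(assays(object)))
        cat("  levels computed (assay 'level')\n")
})

#' PermutationReport: outcome of a permutation test
#'
#' The p-value follows the convention p = (k + 1) / (n + 1) where k is the
#' number of null statistics at least as extreme as the observed value,
#' except that a zero exceedance count is reported as 1/n (so that 0 hits in
#' 1000 permutations prints as 0.001).
#'
#' @slot statistic name of the statistic tested.
#' @slot observed observed value of the statistic (or the threshold probed).
#' @slot nPerm number of permutations.
#' @slot nExceeding number of null draws at least as extreme.
#' @slot pValue reported p-value.
#' @slot seed RNG seed used.
#' @export
setClass("PermutationReport",
    representation(statistic = "character", observed = "numeric",
                   nPerm = "integer", nExceeding = "integer",
                   pValue = "numeric", seed = "integer"))

setValidity("PermutationReport", function(object) {
    if (object@nPerm < 1L) return("nPerm must be positive")
    if (object@nExceeding < 0L || object@nExceeding > object@nPerm)
        return("nExceeding must lie in [0, nPerm]")
    TRUE
})

#' Build a PermutationReport applying the p-value convention
#'
#' @param statistic name of the statistic.
#' @param observed observed value.
#' @param nPerm number of permutations.
#' @param nExceeding count of null statistics at least as extreme.
#' @param seed RNG seed that produced the null.
#' @return A [PermutationReport-class] object.
#' @export
PermutationReport <- function(statistic, observed, nPerm, nExceeding, seed) {
    nPerm <- as.integer(nPerm)
    k <- as.integer(nExceeding)
    p <- if (k == 0L) 1 / nPerm else (k + 1) / (nPerm + 1)
    new("PermutationReport", statistic = statistic,
        observed = as.numeric(observed), nPerm = nPerm, nExceeding = k,
        pValue = p, seed = as.integer(seed))
}

#' @describeIn PermutationReport-class reported p-value
#' @param x a `PermutationReport`
#' @export
pValue <- function(x) x@pValue

setMethod("show", "PermutationReport", function(object) {
    cat(sprintf("Permutation test of %s: observed = %g, %d/%d exceeding, p = %g\n",
                object@statistic, object@observed, object@nExceeding,
                object@nPerm, object@pValue))
})

#' ZoneScan: CAC correlation curve over a grid of TSS vicinities
#'
#' Result of [zoneScan()]: the chromatin abundance coefficient (CAC, a
#' Pearson correlation between grouped normalised region frequency and mean
#' gene expression) for each vicinity half-width of the grid, and the zone
#' of maximal influence Z* (the eligible grid value maximising the
#' correlation, ties broken toward the smaller vicinity).
#'
#' @slot curve `DataFrame` with columns `V`, `r`, `p`, `nPoints`,
#'   `meanCount`, `eligible`.
#' @slot zStar numeric(1), the selected vicinity half-width in bp (`NA` when
#'   no grid point was eligible).
#' @export
setClass("ZoneScan",
    representation(curve = "DataFrame", zStar = "numeric"))

#' @describeIn ZoneScan-class the zone of maximal influence Z* (bp)
#' @param x a `ZoneScan`
#' @export
zStar <- function(x) x@zStar

#' @describeIn ZoneScan-class the full correlation-vs-vicinity curve
#' @export
cacCurve <- function(x) x@curve

setMethod("show", "ZoneScan", function(object) {
    cv <- object@curve
    cat(sprintf("ZoneScan over %d vicinities [%g, %g] kB\n",
                nrow(cv), min(cv$V) / 1e3, max(cv$V) / 1e3))
    if (is.na(object@zStar)) {
        cat("  no eligible vicinity (all correlations undefined)\n")
    } else {
        i <- which(cv$V == object@zStar)
        cat(sprintf("  Z* = %g kB (r = %.3f, p = %.3g, %d frequency groups)\n",
                    object@zStar / 1e3, cv$r[i], cv$p[i], cv$nPoints[i]))
    }
})
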