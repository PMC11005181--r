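# region centre: start + floor(width / 2); for a 100-bp window starting at
# 0-based position s this is s + 50, the natural midpoint of [s, s + 100)
.centres <- function(gr) start(gr) + floor(width(gr) / 2)

#' Accessibility-index profile of regions around a gene set
#'
#' Tiles the strand-aware vicinity [-V, +V] around each focal TSS into bins
#' of `bin` bp and accumulates, per bin j, the number of region centres
#' falling into bin j of gene i divided by the number of expressed genes in
#' gene i's vicinity, averaged over the focal set:
#' index_j = sum_i [ N_AR(V_ij) / N_g(V_i) ] / N_EG. Focal genes whose
#' vicinity contains no expressed gene are skipped and logged. Matched
#' lineage pairing (e.g. mesoderm DARs around mesoderm DEGs) is the
#' caller's responsibility via the inputs.
#'
#' @param regions `GRanges` of regions (centres are used).
#' @param focalGenes `GRanges` of focal TSSs (width-1, stranded).
#' @param expressedGenes `GRanges` of all expressed TSSs (the normalising
#'   set; usually a superset of `focalGenes`).
#' @param V vicinity half-width in bp.
#' @param bin bin width in bp (must divide 2V; default 5000).
#' @return data.frame with `bin_start`, `bin_mid` (strand-aware bp relative
#'   to the TSS) and `index`; the number of skipped vicinities is attached
#'   as attribute `n_skipped`.
#' @export
accessibilityIndexProfile <- function(regions, focalGenes, expressedGenes,
                                      V, bin = 5000) {
    if (bin > V) stop("bin width exceeds the vicinity half-width")
    if ((2 * V) %% bin != 0)
        stop("bin width must divide the vicinity 2V")
    nBins <- as.integer(2 * V / bin)
    centres <- .centres(regions)
    chromR <- as.character(seqnames(regions))
    chromG <- as.character(seqnames(focalGenes))
    tss <- start(focalGenes)
    sign <- ifelse(as.character(strand(focalGenes)) == "-", -1L, 1L)
    expTss <- split(start(expressedGenes),
                    as.character(seqnames(expressedGenes)))
    centSplit <- split(centres, chromR)
    total <- numeric(nBins)
    skipped <- 0L
    for (i in seq_along(focalGenes)) {
        et <- expTss[[chromG[i]]]
        ng <- if (is.null(et)) 0L
              else sum(et >= tss[i] - V & et <= tss[i] + V)
        if (ng == 0L) { skipped <- skipped + 1L; next }
        ct <- centSplit[[chromG[i]]]
        if (!is.null(ct) && length(ct)) {
            rel <- (ct - tss[i]) * sign[i]
            rel <- rel[rel >= -V & rel < V]
            if (length(rel)) {
                idx <- floor((rel + V) / bin) + 1L
                total <- total + tabulate(idx, nBins) / ng
            }
        }
    }
    nEG <- length(focalGenes) - skipped
    if (skipped)
        message("accessibilityIndexProfile: skipped ", skipped,
                " vicinities without expressed genes")
    starts <- seq(-V, V - bin, by = bin)
    out <- data.frame(bin_start = starts, bin_mid = starts + bin / 2,
                      index = if (nEG > 0) total / nEG else total * NA)
    attr(out, "n_skipped") <- skipped
    out
}

# per-gene normalised region frequency: N(V_i) / Ng(V_i); Ng = 0 -> NA
.normalisedFrequency <- function(geneTss, regions, expressedTss, V) {
    chromG <- as.character(seqnames(geneTss))
    tss <- start(geneTss)
    cent <- split(sort(.centres(regions)),
                  as.character(seqnames(regions)))
    expp <- split(sort(start(expressedTss)),
                  as.character(seqnames(expressedTss)))
    N <- Ng <- numeric(length(geneTss))
    for (ch in unique(chromG)) {
        sel <- chromG == ch
        rc <- cent[[ch]]
        et <- expp[[ch]]
        N[sel] <- if (is.null(rc)) 0 else
            findInterval(tss[sel] + V, rc) - findInterval(tss[sel] - V - 1, rc)
        Ng[sel] <- if (is.null(et)) 0 else
            findInterval(tss[sel] + V, et) - findInterval(tss[sel] - V - 1, et)
    }
    f <- ifelse(Ng > 0, N / Ng, NA_real_)
    list(f = f, N = N, Ng = Ng)
}

#' Chromatin abundance coefficient (CAC)
#'
#' For each gene the normalised region frequency f_i = N(V_i) / Ng(V_i) is
#' the number of region centres within the +/-V vicinity of its TSS divided
#' by the number of expressed genes in that vicinity. Genes are grouped by
#' f rounded to `digits` decimals; each group contributes one point
#' (f, mean GE of the group's genes) and the CAC is the Pearson correlation
#' over those points. Fewer than three distinct groups leave the
#' coefficient undefined (`r = NA`, flagged).
#'
#' @param geneTss `GRanges` of the gene set's TSSs.
#' @param ge numeric vector of the gene set's expression (log2 RPKM),
#'   aligned with `geneTss`.
#' @param regions `GRanges` of candidate regions (e.g. matched-lineage
#'   DARs).
#' @param expressedTss `GRanges` of all expressed TSSs (normalising set).
#' @param V vicinity half-width in bp.
#' @param digits rounding applied to f before grouping (default 2).
#' @return list with `V`, `r`, `p`, `nPoints`, `meanCount` (mean N per
#'   gene), `points` (data.frame f / meanGE / n) and `nSkipped` (genes with
#'   empty normalising vicinity).
#' @export
cacScore <- function(geneTss, ge, regions, expressedTss, V, digits = 2) {
    stopifnot(length(ge) == length(geneTss))
    nf <- .normalisedFrequency(geneTss, regions, expressedTss, V)
    ok <- !is.na(nf$f)
    f <- round(nf$f[ok], digits)
    gg <- ge[ok]
    pts <- do.call(rbind, lapply(split(gg, f), function(v)
        data.frame(meanGE = mean(v), n = length(v))))
    pts <- data.frame(f = as.numeric(rownames(pts)), pts, row.names = NULL)
    res <- list(V = V, r = NA_real_, p = NA_real_, nPoints = nrow(pts),
                meanCount = mean(nf$N[ok]), points = pts,
                nSkipped = sum(!ok))
    if (nrow(pts) >= 3L && stats::sd(pts$f) > 0 && stats::sd(pts$meanGE) > 0) {
        ct <- stats::cor.test(pts$f, pts$meanGE)
        res$r <- unname(ct$estimate)
        res$p <- ct$p.value
    }
    res
}

#' Zone-of-influence scan: CAC across a grid of vicinities
#'
#' Computes the CAC for every vicinity half-width of the grid and selects
#' the zone of maximal influence Z* = argmax r among eligible grid points.
#' At small vicinities the region counts are coarse, many genes collapse
#' into the same frequency group and the correlation is estimated from few
#' points, so its sampling noise can spuriously win the argmax; a grid
#' point therefore competes for Z* only when it resolves at least
#' `minPoints` distinct frequency groups. The default asks for a fifth of
#' the gene set (never fewer than 10 groups), in the spirit of scanning
#' only vicinities that keep a workable region density. Ties are broken
#' toward the smaller vicinity, preferring the more local explanation. Run
#' per lineage (and optionally per chromosome) by subsetting the inputs.
#'
#' @inheritParams cacScore
#' @param grid strictly increasing vicinity half-widths in bp (default
#'   20 kB to 400 kB).
#' @param minPoints minimum distinct frequency groups for Z* eligibility;
#'   `NULL` (default) uses max(10, 20% of the gene set). The absolute
#'   minimum for any reported r is 3.
#' @return A [ZoneScan-class].
#' @export
zoneScan <- function(geneTss, ge, regions, expressedTss,
                     grid = c(20, 40, 80, 120, 160, 200, 240, 280, 320,
                              360, 400) * 1000,
                     digits = 2, minPoints = NULL) {
    if (is.unsorted(grid, strictly = TRUE))
        stop("grid must be strictly increasing")
    if (is.null(minPoints))
        minPoints <- max(10, ceiling(0.2 * length(geneTss)))
    rows <- lapply(grid, function(V)
        cacScore(geneTss, ge, regions, expressedTss, V, digits))
    curve <- DataFrame(
        V = grid,
        r = vapply(rows, `[[`, numeric(1), "r"),
        p = vapply(rows, `[[`, numeric(1), "p"),
        nPoints = vapply(rows, function(x) as.integer(x$nPoints),
                         integer(1)),
        meanCount = vapply(rows, `[[`, numeric(1), "meanCount"))
    curve$eligible <- !is.na(curve$r) & curve$nPoints >= minPoints
    if (!any(curve$eligible)) {
        if (all(is.na(curve$r)))
            stop("correlation undefined at every grid vicinity")
        # defined r exists but too few groups everywhere: fall back to the
        # >=3-point minimum rather than fail
        curve$eligible <- !is.na(curve$r)
    }
    el <- which(curve$eligible)
    zs <- grid[el[which.max(curve$r[el])]]   # which.max takes the first tie
    new("ZoneScan", curve = curve, zStar = as.numeric(zs))
}

#' Link genes to regions within Z*, never across TAD boundaries
#'
#' A gene g and region r are linked when the distance between g's TSS and
#' r's centre is at most `zStar` and both fall inside the same TAD. Genes
#' or regions outside every TAD produce no links; the TAD constraint is
#' integral to the method and the TAD set is mandatory. Distances in the
#' output are signed and strand-aware (positive downstream of the TSS).
#'
#' @param genes `GRanges` of gene TSSs (width-1, stranded, `gene_id`).
#' @param regions `GRanges` of regions (optionally carrying a `lineage`
#'   column, which is propagated).
#' @param tads `GRanges` with `tad_id`.
#' @param zStar linking radius in bp (from [zoneScan()] or supplied).
#' @return `GRanges` catalogue: one row per link with the region's
#'   coordinates, the gene's strand and `gene_id`, `distance`, `lineage`,
#'   `tad_id`; ordered by (chrom, start, gene_id).
#' @export
linkRegions <- function(genes, regions, tads, zStar) {
    if (missing(tads) || is.null(tads))
        stop("TAD intervals are required: linking never crosses TAD ",
             "boundaries")
    gTad <- .assignTads(genes, tads)
    centres <- GRanges(seqnames(regions),
                       IRanges(.centres(regions),
                               width = 1L))
    rTad <- .assignTads(centres, tads)
    keepG <- which(!is.na(gTad))
    keepR <- which(!is.na(rTad))
    out <- list()
    for (t in unique(gTad[keepG])) {
        gi <- keepG[gTad[keepG] == t]
        ri <- keepR[rTad[keepR] == t]
        if (!length(ri)) next
        for (g in gi) {
            d <- start(centres)[ri] - start(genes)[g]
            sel <- abs(d) <= zStar
            if (!any(sel)) next
            sgn <- if (as.character(strand(genes))[g] == "-") -1L else 1L
            lk <- regions[ri[sel]]
            mcols(lk) <- NULL
            lk$gene_id <- genes$gene_id[g]
            lk$distance <- d[sel] * sgn
            lk$lineage <- if (!is.null(regions$lineage))
                regions$lineage[ri[sel]] else NA_character_
            lk$tad_id <- tads$tad_id[t]
            strand(lk) <- strand(genes)[g]
            out[[length(out) + 1L]] <- lk
        }
    }
    if (!length(out))
        return(GRanges(gene_id = character(), distance = numeric(),
                       lineage = character(), tad_id = character()))
    cat <- do.call(c, out)
    cat[order(as.character(seqnames(cat)), start(cat), cat$gene_id)]
}

#' Summarise a link catalogue
#' @param links `GRanges` from [linkRegions()].
#' @param far distance considered "far" (default 100 kB).
#' @return list with `n_links`, `n_genes`, `median_abs_distance` and
#'   `frac_beyond` (fraction of links farther than `far`).
#' @export
linkSummary <- function(links, far = 1e5) {
    list(n_links = length(links),
         n_genes = length(unique(links$gene_id)),
         median_abs_distance = if (length(links))
             stats::median(abs(links$distance)) else NA_real_,
         frac_beyond = if (length(links))
             mean(abs(links$distance) > far) else NA_real_)
}

#' Zone scan against histone-mark peaks instead of called regions
#'
#' Identical computation to [zoneScan()] with peak intervals (e.g. H3K27ac
#' enhancers) in place of called accessibility regions; peak centres are
#' used.
#'
#' @inheritParams zoneScan
#' @param peaks `GRanges` of peak intervals.
#' @return A [ZoneScan-class].
#' @export
peakAssociation <- function(geneTss, ge, peaks, expressedTss,
                            grid = c(20, 40, 80, 120, 160, 200, 240, 280,
                                     320, 360, 400) * 1000,
                            digits = 2, minPoints = NULL) {
    if (length(peaks) == 0L) stop("empty peak set")
    zoneScan(geneTss, ge, peaks, expressedTss, grid, digits, minPoints)
}
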