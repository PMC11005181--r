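#' Specification for the synthetic multi-omic dataset generator
#'
#' Bundles and validates every parameter of [generateDataset()]. Defaults
#' model a three-lineage pseudo-bulk gastrulation-stage dataset at desk
#' scale: lineage-dominant genes isolated in their own domains with distal
#' accessible regions planted within a +/-100 kB zone at counts
#' proportional to expression, evenly expressed genes in dense clusters
#' with proximal accessible regions, matching anti-correlated methylation,
#' and alternating domain structure.
#'
#' @param nChrom,chromLength chromosome count and length (bp).
#' @param nGenes total genes; `fracDeg` and `fracSeg` are the planted DEG
#'   and SEG fractions (the remainder is background).
#' @param degBoost linear-scale expression boost of the dominant lineage
#'   for planted DEGs (default 8, i.e. +3 log2).
#' @param degBaseMean,degBaseSd,degLineageSd DEG base expression model
#'   (log2 RPKM): non-dominant lineages are base + N(0, degLineageSd).
#' @param segMean,segSd,segLineageSd SEG expression model: a shared
#'   gene effect N(segMean, segSd) plus tiny per-lineage jitter, so
#'   planted SEGs satisfy Dom <= 0.34 with high probability.
#' @param bgMean,bgSd,bgLineageSd background gene model (lineage-correlated
#'   baseline with moderate jitter).
#' @param nSilentGenes unexpressed genes (all lineages below 0 log2 RPKM),
#'   used as non-expressed motif origins.
#' @param degTadLength,segTadLength mean lengths of DEG-poor and SEG-dense
#'   domains (alternating along each chromosome).
#' @param segClusterSize,segGapMin,segGapMax SEG cluster geometry
#'   (genes per cluster, inter-TSS gap range in bp).
#' @param darRatePerDecile Poisson rate multiplier: a DEG in expression
#'   decile d receives Poisson(darRatePerDecile * d) distal open regions.
#' @param zoneBp half-width of the planted distal zone around DEG TSSs
#'   (default 100,000 bp).
#' @param sarPerSeg,sarWindow proximal open regions per SEG and their
#'   placement half-width around the TSS (default 2 within +/-2000 bp).
#' @param nBackgroundRegions,nBackgroundMeth uniformly placed background
#'   accessibility / methylation windows per chromosome.
#' @param muCov,muGc,muCpg Poisson means of reads per window, GpC
#'   dinucleotides per 100-bp window and CpGs per 500-bp window.
#' @param darLevelHigh,darLevelLow accessibility level of a planted DAR in
#'   the dominant / other lineages.
#' @param sarLevel accessibility level of planted SARs (all lineages).
#' @param bgLevelRange accessibility level range of background windows.
#' @param methHypo,methHigh,bgMeth methylation fractions: hypomethylated
#'   lineage at a planted region, methylated lineages, and background.
#' @param darMethFraction fraction of planted DARs that carry a matching
#'   hypomethylated 500-bp window.
#' @param accWidth,methWidth window widths (100 / 500 bp).
#' @param motifs list of [generateMotifLists()] parameters.
#' @param seed RNG seed; identical spec and seed give identical output.
#' @return a validated `SimulationSpec` list.
#' @export
simulationSpec <- function(nChrom = 3, chromLength = 2.4e7, nGenes = 300,
                           fracDeg = 0.3, fracSeg = 0.3,
                           degBoost = 8, degBaseMean = 2, degBaseSd = 1,
                           degLineageSd = 0.5,
                           segMean = 5, segSd = 1.5, segLineageSd = 0.01,
                           bgMean = 4, bgSd = 2.5, bgLineageSd = 0.4,
                           nSilentGenes = 20,
                           degTadLength = 6e5, segTadLength = 3e5,
                           segClusterSize = 5, segGapMin = 2000,
                           segGapMax = 10000,
                           darRatePerDecile = 5, zoneBp = 1e5,
                           sarPerSeg = 2, sarWindow = 2000,
                           nBackgroundRegions = 300, nBackgroundMeth = 300,
                           muCov = 50, muGc = 15, muCpg = 30,
                           darLevelHigh = 0.85, darLevelLow = 0.05,
                           sarLevel = 0.55, bgLevelRange = c(0.05, 0.3),
                           methHypo = 0.1, methHigh = 0.9, bgMeth = 0.8,
                           darMethFraction = 0.2,
                           accWidth = 100, methWidth = 500,
                           motifs = list(nMotifs = 60, withinOverlap = 0.8,
                                         betweenOverlap = 0.2,
                                         gcSplit = 0.9, fracSilent = 0.25),
                           seed = 1) {
    spec <- as.list(environment())
    if (spec$fracDeg + spec$fracSeg > 1)
        stop("planted fractions must sum to at most 1")
    rates <- c(degBoost, darRatePerDecile, muCov, muGc, muCpg, zoneBp)
    if (any(rates <= 0)) stop("all rate parameters must be positive")
    if (spec$nChrom < 1 || spec$nGenes < 1) stop("need >= 1 chromosome/gene")
    class(spec) <- "SimulationSpec"
    spec
}

# alternating DEG/SEG-cluster domain tiling across chromosomes; errors when
# the requested genes cannot fit the genome
.tileTads <- function(nDegTads, nSegTads, spec) {
    types <- character(nDegTads + nSegTads)
    if (length(types) == 0L) return(NULL)
    # interleave as evenly as possible
    o <- order(c(if (nDegTads) (seq_len(nDegTads) - 0.5) / nDegTads,
                 if (nSegTads) (seq_len(nSegTads) - 0.25) / nSegTads))
    types <- c(rep("deg", nDegTads), rep("seg", nSegTads))[o]
    lens <- round(ifelse(types == "deg", spec$degTadLength,
                         spec$segTadLength) * stats::runif(length(types),
                                                           0.8, 1.2) / 100) * 100
    gaps <- round(stats::runif(length(types), 2e4, 6e4))
    chrom <- integer(length(types))
    starts <- numeric(length(types))
    ch <- 1L
    at <- gaps[1]
    for (i in seq_along(types)) {
        if (at + lens[i] > spec$chromLength) {
            ch <- ch + 1L
            at <- gaps[i]
            if (ch > spec$nChrom || at + lens[i] > spec$chromLength)
                stop("planted genes cannot fit the configured chromosome ",
                     "length; increase chromLength or nChrom")
        }
        chrom[i] <- ch
        starts[i] <- at
        at <- at + lens[i] + gaps[i]
    }
    GRanges(paste0("chr", chrom), IRanges(starts + 1, width = lens),
            tad_id = sprintf("tad_%05d", seq_along(types)), type = types)
}

.snap <- function(pos, width, chromLength)
    pmin(pmax(floor(pos / width) * width, 0), chromLength - width)

# count matrices for a set of windows given target levels (rows x 3)
.windowCounts <- function(n, levels, muCov, muDinuc) {
    reads <- matrix(stats::rpois(3 * n, muCov), n, 3)
    tot <- matrix(stats::rpois(3 * n, muDinuc), n, 3)
    met <- matrix(stats::rbinom(3 * n, as.vector(tot), as.vector(levels)),
                  n, 3)
    list(reads = reads, tot = tot, met = met)
}

#' Generate a complete synthetic multi-omic dataset with ground truth
#'
#' Produces, from a [simulationSpec()], a gene annotation with planted
#' DEG/SEG/background classes, a three-lineage log2 RPKM expression table,
#' accessibility (100 bp) and methylation (500 bp) signal windows with
#' planted differential and similar regions, TAD intervals, eight enriched
#' motif lists and the ground truth needed for parameter-recovery tests.
#' All outputs are deterministic functions of the spec (including its
#' seed).
#'
#' @param spec a `SimulationSpec`.
#' @return list with `annotation` (`GRanges`), `expression` (matrix),
#'   `accWindows`, `methWindows` ([SignalWindows-class]), `tads`
#'   (`GRanges`), `motifLists` (named list of data.frames) and `truth`
#'   (list: `genes` DataFrame, `regions` GRanges, `zone_bp`).
#' @export
generateDataset <- function(spec = simulationSpec()) {
    stopifnot(inherits(spec, "SimulationSpec"))
    set.seed(spec$seed)
    nDegPerLin <- floor(spec$nGenes * spec$fracDeg / 3)
    nDeg <- 3L * nDegPerLin
    nSeg <- round(spec$nGenes * spec$fracSeg)
    nSegTads <- if (nSeg) ceiling(nSeg / spec$segClusterSize) else 0L
    nBg <- spec$nGenes - nDeg - nSeg
    tads <- .tileTads(nDeg, nSegTads, spec)

    geneRows <- list()
    addGene <- function(chrom, pos, class, lineage) {
        geneRows[[length(geneRows) + 1L]] <<- data.frame(
            chrom = chrom, pos = pos, class = class, lineage = lineage)
    }
    if (!is.null(tads)) {
        degTads <- which(tads$type == "deg")
        lineages <- rep(.LINEAGES, length.out = length(degTads))
        for (k in seq_along(degTads)) {
            t <- degTads[k]
            centre <- start(tads)[t] +
                round(width(tads)[t] * stats::runif(1, 0.35, 0.65))
            addGene(as.character(seqnames(tads))[t], centre,
                    paste0("DEG_", .LINEAGE_NAMES[lineages[k]]),
                    lineages[k])
        }
        segTads <- which(tads$type == "seg")
        placed <- 0L
        for (t in segTads) {
            k <- min(spec$segClusterSize, nSeg - placed)
            if (k <= 0L) break
            gaps <- round(stats::runif(k - 1, spec$segGapMin,
                                       spec$segGapMax))
            offs <- cumsum(c(0, gaps))
            centre <- start(tads)[t] + round(width(tads)[t] / 2)
            pos <- centre - round(max(offs) / 2) + offs
            for (p in pos)
                addGene(as.character(seqnames(tads))[t], p, "SEG", "all")
            placed <- placed + k
        }
    }
    for (i in seq_len(nBg))
        addGene(paste0("chr", sample.int(spec$nChrom, 1)),
                sample.int(spec$chromLength - 1, 1), "background", "none")
    for (i in seq_len(spec$nSilentGenes))
        addGene(paste0("chr", sample.int(spec$nChrom, 1)),
                sample.int(spec$chromLength - 1, 1), "silent", "none")
    genes <- do.call(rbind, geneRows)
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)

    # expression (log2 RPKM)
    n <- nrow(genes)
    expr <- matrix(NA_real_, n, 3, dimnames = list(genes$gene_id, .LINEAGES))
    for (i in seq_len(n)) {
        cl <- genes$class[i]
        if (startsWith(cl, "DEG")) {
            b <- stats::rnorm(1, spec$degBaseMean, spec$degBaseSd)
            v <- b + stats::rnorm(3, 0, spec$degLineageSd)
            li <- match(genes$lineage[i], .LINEAGES)
            v[li] <- b + log2(spec$degBoost) +
                stats::rnorm(1, 0, spec$degLineageSd)
        } else if (cl == "SEG") {
            g <- stats::rnorm(1, spec$segMean, spec$segSd)
            v <- g + stats::rnorm(3, 0, spec$segLineageSd)
        } else if (cl == "silent") {
            g <- stats::rnorm(1, -2, 0.5)
            v <- g + stats::rnorm(3, 0, 0.3)
        } else {
            g <- stats::rnorm(1, spec$bgMean, spec$bgSd)
            v <- g + stats::rnorm(3, 0, spec$bgLineageSd)
        }
        expr[i, ] <- v
    }

    annotation <- GRanges(genes$chrom, IRanges(genes$pos + 1L, width = 1L),
                          strand = genes$strand, gene_id = genes$gene_id,
                          class_label = ifelse(
                              genes$class %in% c("background", "silent"),
                              "unclassified", genes$class))
    annotation <- GenomicRanges::sort(annotation, ignore.strand = TRUE)

    # accessibility windows: distal DARs around DEGs (counts proportional
    # to the expression decile), proximal SARs at SEG promoters, uniform
    # background
    accRows <- list()
    truthRegions <- list()
    addAcc <- function(chrom, startPos, levels, class, lineage, target) {
        accRows[[length(accRows) + 1L]] <<- data.frame(
            chrom = chrom, start = startPos,
            l1 = levels[1], l2 = levels[2], l3 = levels[3])
        truthRegions[[length(truthRegions) + 1L]] <<- data.frame(
            chrom = chrom, start = startPos, width = spec$accWidth,
            class = class, lineage = lineage, target_gene = target)
    }
    for (L in .LINEAGES) {
        sel <- genes$class == paste0("DEG_", .LINEAGE_NAMES[L])
        if (!any(sel)) next
        ge <- expr[genes$gene_id[sel], L]
        dec <- ceiling(rank(ge, ties.method = "first") / length(ge) * 10)
        counts <- stats::rpois(length(ge), spec$darRatePerDecile * dec)
        li <- match(L, .LINEAGES)
        lev <- rep(spec$darLevelLow, 3)
        lev[li] <- spec$darLevelHigh
        gsel <- which(sel)
        for (j in seq_along(gsel)) {
            if (counts[j] == 0L) next
            pos <- .snap(genes$pos[gsel[j]] +
                             round(stats::runif(counts[j], -spec$zoneBp,
                                                spec$zoneBp)),
                         spec$accWidth, spec$chromLength)
            for (p in unique(pos))
                addAcc(genes$chrom[gsel[j]], p, lev, "DAR", L,
                       genes$gene_id[gsel[j]])
        }
    }
    for (i in which(genes$class == "SEG")) {
        pos <- .snap(genes$pos[i] + round(stats::runif(spec$sarPerSeg,
                                                       -spec$sarWindow,
                                                       spec$sarWindow)),
                     spec$accWidth, spec$chromLength)
        for (p in unique(pos))
            addAcc(genes$chrom[i], p, rep(spec$sarLevel, 3), "SAR", "all",
                   genes$gene_id[i])
    }
    for (ch in seq_len(spec$nChrom)) {
        pos <- .snap(stats::runif(spec$nBackgroundRegions, 0,
                                  spec$chromLength),
                     spec$accWidth, spec$chromLength)
        base <- stats::runif(spec$nBackgroundRegions, spec$bgLevelRange[1],
                             spec$bgLevelRange[2])
        for (j in seq_along(pos))
            addAcc(paste0("chr", ch), pos[j], rep(base[j], 3),
                   "background", "all", NA_character_)
    }
    acc <- do.call(rbind, accRows)
    truthAcc <- do.call(rbind, truthRegions)
    dup <- duplicated(paste(acc$chrom, acc$start))
    acc <- acc[!dup, ]
    truthAcc <- truthAcc[!dup, ]
    cw <- .windowCounts(nrow(acc), as.matrix(acc[, c("l1", "l2", "l3")]),
                        spec$muCov, spec$muGc)
    accW <- SignalWindows(
        GRanges(acc$chrom, IRanges(acc$start + 1L, width = spec$accWidth)),
        reads = cw$reads, dinucTotal = cw$tot, dinucMeth = cw$met)

    # methylation windows, anti-correlated with accessibility at planted
    # regions (hypomethylated where open)
    methRows <- list()
    addMeth <- function(chrom, startPos, m, class, lineage, target) {
        methRows[[length(methRows) + 1L]] <<- data.frame(
            chrom = chrom, start = startPos, l1 = m[1], l2 = m[2],
            l3 = m[3], class = class, lineage = lineage,
            target_gene = target)
    }
    darIdx <- which(truthAcc$class == "DAR")
    if (length(darIdx)) {
        pick <- darIdx[stats::runif(length(darIdx)) < spec$darMethFraction]
        for (i in pick) {
            m <- rep(spec$methHigh, 3)
            m[match(truthAcc$lineage[i], .LINEAGES)] <- spec$methHypo
            addMeth(truthAcc$chrom[i],
                    .snap(truthAcc$start[i], spec$methWidth,
                          spec$chromLength),
                    m, "DhMR", truthAcc$lineage[i], truthAcc$target_gene[i])
        }
    }
    for (i in which(genes$class == "SEG"))
        addMeth(genes$chrom[i],
                .snap(genes$pos[i], spec$methWidth, spec$chromLength),
                rep(spec$methHypo, 3), "ShMR", "all", genes$gene_id[i])
    for (ch in seq_len(spec$nChrom)) {
        pos <- .snap(stats::runif(spec$nBackgroundMeth, 0,
                                  spec$chromLength),
                     spec$methWidth, spec$chromLength)
        for (p in pos)
            addMeth(paste0("chr", ch), p, rep(spec$bgMeth, 3),
                    "background", "all", NA_character_)
    }
    meth <- do.call(rbind, methRows)
    dup <- duplicated(paste(meth$chrom, meth$start))
    meth <- meth[!dup, ]
    cwm <- .windowCounts(nrow(meth), as.matrix(meth[, c("l1", "l2", "l3")]),
                         spec$muCov, spec$muCpg)
    methW <- SignalWindows(
        GRanges(meth$chrom, IRanges(meth$start + 1L,
                                    width = spec$methWidth)),
        reads = cwm$reads, dinucTotal = cwm$tot, dinucMeth = cwm$met)

    planted <- rbind(
        cbind(truthAcc[truthAcc$class != "background", ],
              width = spec$accWidth)[, c("chrom", "start", "width", "class",
                                         "lineage", "target_gene")],
        data.frame(chrom = meth$chrom, start = meth$start,
                   width = spec$methWidth, class = meth$class,
                   lineage = meth$lineage,
                   target_gene = meth$target_gene)[
                       meth$class != "background", ])
    truthGr <- GRanges(planted$chrom,
                       IRanges(planted$start + 1L, width = planted$width),
                       class = planted$class, lineage = planted$lineage,
                       target_gene = planted$target_gene)

    # origin pools for the motif generator; lineages or classes without
    # planted genes fall back to expressed background genes
    expressedBg <- genes$gene_id[genes$class == "background"]
    orElse <- function(x, y) if (length(x)) x else y
    pools <- list(
        deg = stats::setNames(lapply(.LINEAGES, function(L) orElse(
            genes$gene_id[genes$class == paste0("DEG_", .LINEAGE_NAMES[L])],
            expressedBg)), .LINEAGES),
        seg = orElse(genes$gene_id[genes$class == "SEG"], expressedBg),
        silent = genes$gene_id[genes$class == "silent"])
    motifLists <- do.call(generateMotifLists,
                          c(spec$motifs, list(originPools = pools)))

    if (is.null(tads))
        tads <- GRanges(tad_id = character(), type = character())
    list(annotation = annotation, expression = expr, accWindows = accW,
         methWindows = methW, tads = tads, motifLists = motifLists,
         truth = list(genes = DataFrame(gene_id = genes$gene_id,
                                        class = genes$class,
                                        lineage = genes$lineage),
                      regions = truthGr, zone_bp = spec$zoneBp))
}

.randomConsensus <- function(n, gcRich) {
    lens <- sample(6:12, n, replace = TRUE)
    vapply(seq_len(n), function(i) {
        p <- if (gcRich[i]) c(0.15, 0.35, 0.35, 0.15)
             else c(0.30, 0.20, 0.20, 0.30)
        paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE,
                     prob = p), collapse = "")
    }, character(1))
}

#' Generate the eight enriched-motif lists with controlled overlap
#'
#' Builds two motif grammars (developmental and housekeeping) and eight
#' lists: three DEG-enhancer, three DEG core-promoter, one SEG-enhancer and
#' one SEG core-promoter. Lists of the same grammar share a core of
#' `withinOverlap * nMotifs` motifs; the two grammars share
#' `betweenOverlap * nMotifs` motifs (which must not exceed the core size).
#' SEG-grammar consensi are drawn GC-rich at rate `gcSplit`, DEG-grammar at
#' rate `1 - gcSplit`. Each motif's origin TF gene is sampled from the
#' matching pool, or from the silent pool at rate `fracSilent` so a known
#' fraction of motifs fails the downstream expression filter.
#'
#' @param nMotifs motifs per list.
#' @param withinOverlap,betweenOverlap shared fraction within a grammar and
#'   between the two grammars.
#' @param gcSplit GC-rich rate of the SEG grammar.
#' @param fracSilent fraction of motifs assigned a non-expressed origin.
#' @param originPools optional list with `deg` (list of gene-id vectors per
#'   lineage), `seg` and `silent` id vectors; synthetic TF ids are
#'   fabricated when absent.
#' @param seed RNG seed (ignored when called from [generateDataset()],
#'   which seeds globally).
#' @return named list of eight motif data.frames
#'   (enh_ect/enh_end/enh_mes/cp_ect/cp_end/cp_mes/enh_seg/cp_seg).
#' @export
generateMotifLists <- function(nMotifs = 60, withinOverlap = 0.8,
                               betweenOverlap = 0.2, gcSplit = 0.9,
                               fracSilent = 0.25, originPools = NULL,
                               seed = NULL) {
    if (withinOverlap < 0 || withinOverlap > 1 ||
        betweenOverlap < 0 || betweenOverlap > 1)
        stop("overlap fractions must lie in [0, 1]")
    nShared <- round(withinOverlap * nMotifs)
    nCommon <- round(betweenOverlap * nMotifs)
    if (nCommon > nShared)
        stop("between-grammar overlap ", betweenOverlap,
             " infeasible with within-grammar overlap ", withinOverlap)
    if (!is.null(seed)) set.seed(seed)
    nUnique <- nMotifs - nShared
    listNames <- c(paste0("enh_", .LINEAGES), paste0("cp_", .LINEAGES),
                   "enh_seg", "cp_seg")
    grammar <- c(rep("deg", 6), rep("seg", 2))
    nPerGrammar <- (nShared - nCommon) +
        nUnique * c(deg = 6L, seg = 2L)
    total <- nCommon + sum(nPerGrammar)
    ids <- sprintf("mot_%04d", seq_len(total))
    isCommon <- seq_len(total) <= nCommon
    grammarOf <- c(rep("common", nCommon),
                   rep("deg", nPerGrammar["deg"]),
                   rep("seg", nPerGrammar["seg"]))
    gcRich <- stats::runif(total) < ifelse(
        grammarOf == "seg", gcSplit,
        ifelse(grammarOf == "deg", 1 - gcSplit, 0.5))
    consensus <- .randomConsensus(total, gcRich)
    if (is.null(originPools))
        originPools <- list(
            deg = stats::setNames(
                lapply(.LINEAGES, function(L)
                    sprintf("tf_%s_%03d", L, 1:50)), .LINEAGES),
            seg = sprintf("tf_seg_%03d", 1:50),
            silent = sprintf("tf_silent_%03d", 1:50))
    sampleOrigin <- function(k, pool, silent) {
        useSilent <- stats::runif(k) < fracSilent & length(silent) > 0
        out <- sample(pool, k, replace = TRUE)
        if (any(useSilent))
            out[useSilent] <- sample(silent, sum(useSilent), replace = TRUE)
        out
    }
    # fixed origin per motif: common/SEG motifs from the SEG pool, DEG
    # motifs from a lineage pool chosen per motif
    origin <- character(total)
    degLin <- sample(.LINEAGES, total, replace = TRUE)
    for (i in seq_len(total)) {
        origin[i] <- if (grammarOf[i] == "deg")
            sampleOrigin(1, originPools$deg[[degLin[i]]],
                         originPools$silent)
        else sampleOrigin(1, originPools$seg, originPools$silent)
    }
    coreIdx <- list(
        deg = c(which(isCommon), which(grammarOf == "deg")[
            seq_len(nShared - nCommon)]),
        seg = c(which(isCommon), which(grammarOf == "seg")[
            seq_len(nShared - nCommon)]))
    uniqueIdx <- list(
        deg = setdiff(which(grammarOf == "deg"),
                      coreIdx$deg),
        seg = setdiff(which(grammarOf == "seg"), coreIdx$seg))
    out <- list()
    used <- list(deg = 0L, seg = 0L)
    for (k in seq_along(listNames)) {
        g <- grammar[k]
        uniq <- if (nUnique > 0)
            uniqueIdx[[g]][used[[g]] + seq_len(nUnique)] else integer()
        used[[g]] <- used[[g]] + nUnique
        idx <- c(coreIdx[[g]], uniq)
        out[[listNames[k]]] <- data.frame(
            motif = ids[idx],
            score = round(sort(stats::runif(length(idx), 3, 10),
                               decreasing = TRUE), 4),
            consensus = consensus[idx], origin_gene = origin[idx],
            stringsAsFactors = FALSE)
    }
    out
}

#' Synthetic scenario for calibrating the zone-of-influence scan
#'
#' Places `nGenes` isolated lineage-dominant genes on one synthetic
#' chromosome (jittered regular spacing, so neighbouring genes' region
#' clouds do not interfere), assigns dominant-lineage expression, and
#' plants Poisson(`ratePerDecile` x expression decile) open regions
#' uniformly within +/-`zoneBp` of each TSS plus `nBackground` uniform
#' background regions. The resulting inputs drive [zoneScan()] directly.
#'
#' @param nGenes,chromLength scenario size (defaults 300 genes / 50 Mb).
#' @param ratePerDecile Poisson multiplier for planted region counts.
#' @param zoneBp planted zone half-width (default 100 kB).
#' @param nBackground uniform background regions.
#' @param geRange dominant-lineage log2 RPKM range (uniform).
#' @param seed RNG seed.
#' @return list with `tss` (`GRanges`), `ge` (numeric) and `regions`
#'   (`GRanges`, width 100).
#' @export
simulateLinkingScenario <- function(nGenes = 300, chromLength = 5e7,
                                    ratePerDecile = 5, zoneBp = 1e5,
                                    nBackground = 500, geRange = c(2, 5),
                                    seed = 1) {
    set.seed(seed)
    gaps <- (chromLength / nGenes) * (0.5 + stats::runif(nGenes))
    pos <- round(cumsum(gaps) * chromLength / sum(gaps) * 0.999)
    ge <- stats::runif(nGenes, geRange[1], geRange[2])
    dec <- ceiling(rank(ge, ties.method = "first") / nGenes * 10)
    counts <- stats::rpois(nGenes, ratePerDecile * dec)
    planted <- unlist(lapply(seq_len(nGenes), function(i)
        if (counts[i] > 0)
            pmax(1, pmin(chromLength - 100,
                         pos[i] + round(stats::runif(counts[i], -zoneBp,
                                                     zoneBp))))
        else integer()))
    bg <- sample.int(chromLength - 100, nBackground)
    regs <- sort(c(planted, bg))
    list(tss = GRanges("chr1", IRanges(pos, width = 1L), strand = "+",
                       gene_id = sprintf("g%04d", seq_len(nGenes))),
         ge = ge,
         regions = GRanges("chr1", IRanges(regs, width = 100L)))
}
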