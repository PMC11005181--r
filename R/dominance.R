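#' Berger-Parker dominance index
#'
#' Dom = max(v) / sum(v) for a vector of three non-negative values on the
#' linear scale. An even triple gives 1/3 (prints as 0.33); a single
#' non-zero entry gives 1. The index is scale-invariant: Dom(c * v) = Dom(v)
#' for any c > 0. All-zero input is undefined and returns `NA` so callers
#' can exclude (not classify) such genes.
#'
#' @param x numeric vector of length 3, or a numeric matrix with 3 columns
#'   (one row per gene/window), on the linear scale.
#' @return A numeric scalar (vector input) or vector (matrix input) in
#'   [1/3, 1], `NA` where all three values are zero.
#' @examples
#' dominanceIndex(c(1, 1, 1))   # 1/3
#' dominanceIndex(c(3, 1, 1))   # 0.6
#' dominanceIndex(c(5, 0, 0))   # 1
#' @export
dominanceIndex <- function(x) {
    if (is.matrix(x)) {
        if (ncol(x) != 3L) stop("matrix input must have 3 columns")
        if (any(x < 0, na.rm = TRUE)) stop("values must be non-negative")
        tot <- rowSums(x)
        d <- do.call(pmax, as.data.frame(x)) / tot
        d[tot == 0] <- NA_real_
        return(unname(d))
    }
    if (length(x) != 3L) stop("expected exactly three lineage values")
    if (any(x < 0)) stop("values must be non-negative")
    if (sum(x) == 0) return(NA_real_)
    max(x) / sum(x)
}

# argmax lineage per row, NA on all-zero rows; ties go to the first lineage
.rowArgmaxLineage <- function(m) {
    idx <- max.col(m, ties.method = "first")
    idx[rowSums(m) == 0] <- NA_integer_
    .LINEAGES[idx]
}

#' Classify genes into DEGs, SEGs and unclassified by dominance
#'
#' Expression is supplied in log2 RPKM and linearized (2^GE) before the
#' dominance index is computed, so that ratios are taken on a meaningful
#' scale and an even triple gives Dom = 1/3 exactly. A gene is a
#' lineage-specific DEG when Dom >= `dHigh` and its dominant-lineage log2
#' RPKM exceeds `minExpr`; a SEG when Dom <= `dLow` and all three log2 RPKM
#' values exceed `segMinExpr`; otherwise unclassified. Both dominance bounds
#' are inclusive so the worked threshold values classify. The classes
#' partition all genes with a defined dominance.
#'
#' @param expr numeric matrix of log2 RPKM, genes x lineages
#'   (columns ect/end/mes). `NA` cells are treated as "not expressed"
#'   (linear 0).
#' @param annotation optional `GRanges` gene annotation; when given, every
#'   expression row must resolve to an annotated gene.
#' @param dHigh,dLow dominance thresholds for DEG (>= 0.6) and SEG (<= 0.34).
#' @param minExpr DEG expression floor: dominant-lineage log2 RPKM must
#'   exceed this (default 2).
#' @param segMinExpr SEG expression floor: every lineage's log2 RPKM must
#'   exceed this (default 0; SEGs are expressed everywhere).
#' @return `DataFrame` with columns `gene_id`, `dom`, `lineage` (argmax) and
#'   `class_label`.
#' @examples
#' ge <- rbind(log2(c(6, 2, 2)), log2(c(10, 10, 10)), log2(c(2, 1, 1)))
#' rownames(ge) <- c("a", "b", "c"); colnames(ge) <- c("ect", "end", "mes")
#' classifyGenes(ge)$class_label  # DEG_ectoderm, SEG, unclassified
#' @export
classifyGenes <- function(expr, annotation = NULL, dHigh = 0.6, dLow = 0.34,
                          minExpr = 2, segMinExpr = 0) {
    expr <- .checkExpr(expr)
    if (!is.null(annotation)) {
        missing <- setdiff(rownames(expr), annotation$gene_id)
        if (length(missing))
            stop("genes absent from annotation: ",
                 paste(missing, collapse = ", "))
    }
    if (dHigh <= dLow || dLow < 1 / 3)
        stop("need dHigh > dLow >= 1/3")
    loge <- expr
    loge[is.na(loge)] <- -Inf
    lin <- 2^loge
    dom <- dominanceIndex(lin)
    lineage <- .rowArgmaxLineage(lin)
    domExpr <- loge[cbind(seq_len(nrow(loge)),
                          match(lineage, .LINEAGES))]
    cls <- rep("unclassified", nrow(expr))
    isDeg <- !is.na(dom) & dom >= dHigh & domExpr > minExpr
    isSeg <- !is.na(dom) & dom <= dLow &
        rowSums(loge > segMinExpr) == 3L
    cls[isDeg] <- paste0("DEG_", .LINEAGE_NAMES[lineage[isDeg]])
    cls[isSeg] <- "SEG"
    cls[is.na(dom)] <- NA_character_
    DataFrame(gene_id = rownames(expr), dom = dom, lineage = lineage,
              class_label = cls)
}

.checkExpr <- function(expr) {
    expr <- as.matrix(expr)
    if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
    if (!identical(colnames(expr), .LINEAGES)) {
        if (ncol(expr) != 3L)
            stop("expression matrix must have 3 lineage columns")
        colnames(expr) <- .LINEAGES
    }
    expr
}

#' Fold-change + MAD-score DEG flagging (alternative strategy)
#'
#' A gene is flagged for lineage L when its linear-scale expression exceeds
#' `fold` times the expression in each of the two other lineages and its
#' log2 ratio is an outlier of the genome-wide ratio distribution for both
#' comparisons: robust z = (lr - median(lr)) / (1.4826 * MAD(lr)) above the
#' two-sided `alpha` normal quantile. When the MAD collapses to zero the
#' flagging falls back to rank-based tail selection with a warning. Returned
#' flags are kept separate from the dominance labels; when those are
#' supplied, Jaccard agreement between the two DEG definitions is reported.
#'
#' @param expr log2 RPKM matrix (genes x ect/end/mes).
#' @param fold linear fold-change each other lineage must be exceeded by.
#' @param alpha two-sided significance level for the robust z-score.
#' @param domClasses optional result of [classifyGenes()] for the agreement
#'   statistic.
#' @return list with `flags` (`DataFrame`: gene_id, one logical column per
#'   lineage, `flagged_lineage`) and `jaccard` (named numeric: overall and
#'   per-lineage agreement with the dominance DEGs, `NA` without
#'   `domClasses`).
#' @export
madDegStrategy <- function(expr, fold = 3, alpha = 0.01, domClasses = NULL) {
    expr <- .checkExpr(expr)
    zcut <- stats::qnorm(1 - alpha / 2)
    flags <- matrix(FALSE, nrow(expr), 3L,
                    dimnames = list(rownames(expr), .LINEAGES))
    for (L in .LINEAGES) {
        others <- setdiff(.LINEAGES, L)
        ok <- rep(TRUE, nrow(expr))
        for (o in others) {
            lr <- expr[, L] - expr[, o]           # log2 ratio
            s <- stats::mad(lr)                   # 1.4826 * MAD
            if (s == 0) {
                warning("MAD of log-ratios is zero for ", L, " vs ", o,
                        "; falling back to rank-based flagging")
                z <- stats::qnorm(rank(lr) / (length(lr) + 1))
            } else {
                z <- (lr - stats::median(lr)) / s
            }
            ok <- ok & (lr > log2(fold)) & (z > zcut)
        }
        flags[, L] <- ok
    }
    fl <- .LINEAGES[max.col(flags, ties.method = "first")]
    fl[rowSums(flags) == 0] <- NA_character_
    jac <- c(overall = NA_real_,
             stats::setNames(rep(NA_real_, 3), .LINEAGES))
    if (!is.null(domClasses)) {
        jacFun <- function(a, b) {
            u <- length(union(a, b))
            if (u == 0) return(NA_real_)
            length(intersect(a, b)) / u
        }
        domDeg <- domClasses$gene_id[startsWith(domClasses$class_label %|NA|%
                                                    "", "DEG")]
        jac["overall"] <- jacFun(rownames(expr)[rowSums(flags) > 0], domDeg)
        for (L in .LINEAGES) {
            dl <- domClasses$gene_id[
                (domClasses$class_label %|NA|% "") ==
                    paste0("DEG_", .LINEAGE_NAMES[L])]
            jac[L] <- jacFun(rownames(expr)[flags[, L]], dl)
        }
    }
    list(flags = DataFrame(gene_id = rownames(expr),
                           ect = flags[, "ect"], end = flags[, "end"],
                           mes = flags[, "mes"], flagged_lineage = fl),
         jaccard = jac)
}

`%|NA|%` <- function(x, repl) { x[is.na(x)] <- repl; x }

#' Dominance-threshold permutation test
#'
#' Assembles `nPerm` random expression triples by drawing, independently and
#' uniformly within each lineage, one expression value from the pool of
#' eligible genes, then computes the dominance index of each linearized
#' triple. For the SEG-side test (direction `"le"`) the pool contains genes
#' expressed in at least one lineage (log2 RPKM > `exprFloor`); for the
#' DEG-side test set `conditionLineage` so the pool is restricted to genes
#' with log2 RPKM > `minExpr` in that lineage, and a permuted triple counts
#' as a hit only when that lineage is also the dominant one. The p-value
#' follows the [PermutationReport()] convention.
#'
#' @param expr log2 RPKM matrix (genes x ect/end/mes).
#' @param threshold dominance threshold probed (e.g. 0.34 or 0.6).
#' @param direction `"le"`: hits are permuted triples with Dom <= threshold;
#'   `"ge"`: Dom >= threshold.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param conditionLineage optional lineage ("ect"/"end"/"mes") conditioning
#'   the pool and the dominance direction.
#' @param minExpr expression floor for the conditioned pool (log2 RPKM > 2).
#' @param exprFloor floor defining "expressed" for the unconditioned pool.
#' @return A [PermutationReport-class].
#' @export
dominancePermutationTest <- function(expr, threshold,
                                     direction = c("le", "ge"),
                                     nPerm = 1000, seed = 1,
                                     conditionLineage = NULL,
                                     minExpr = 2, exprFloor = 0) {
    expr <- .checkExpr(expr)
    direction <- match.arg(direction)
    expr[is.na(expr)] <- -Inf
    if (is.null(conditionLineage)) {
        pool <- expr[apply(expr, 1L, max) > exprFloor, , drop = FALSE]
    } else {
        conditionLineage <- match.arg(conditionLineage, .LINEAGES)
        pool <- expr[expr[, conditionLineage] > minExpr, , drop = FALSE]
    }
    if (nrow(pool) < 10L)
        stop("permutation pool holds fewer than 10 genes (",
             nrow(pool), ")")
    set.seed(seed)
    draws <- vapply(.LINEAGES,
                    function(L) sample(pool[, L], nPerm, replace = TRUE),
                    numeric(nPerm))
    lin <- 2^draws
    dom <- dominanceIndex(lin)
    hits <- if (direction == "le") dom <= threshold else dom >= threshold
    if (!is.null(conditionLineage) && direction == "ge")
        hits <- hits & .rowArgmaxLineage(lin) == conditionLineage
    PermutationReport(
        statistic = paste0("Dom ", if (direction == "le") "<= " else ">= ",
                           threshold,
                           if (!is.null(conditionLineage))
                               paste0(" | ", conditionLineage) else ""),
        observed = threshold, nPerm = nPerm,
        nExceeding = sum(hits, na.rm = TRUE), seed = seed)
}

#' Permutation test for overlap enrichment of two gene/region sets
#'
#' Compares the observed overlap of `setA` and `setB` with the overlap of
#' random draws of `|setA|` elements from the universe; the enrichment fold
#' is the observed overlap over the mean null overlap (whose expectation is
#' |A||B|/|U|).
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible identifiers.
#' @param nPerm,seed permutation count and RNG seed.
#' @param alternative `"greater"` tests enrichment, `"less"` depletion.
#' @return list with `overlap`, `expected` (mean null overlap), `fold` and
#'   `report` (a [PermutationReport-class]).
#' @export
setEnrichmentPermutation <- function(setA, setB, universe, nPerm = 1000,
                                     seed = 1,
                                     alternative = c("greater", "less")) {
    alternative <- match.arg(alternative)
    if (length(setA) > length(universe))
        stop("setA is larger than the universe")
    if (!all(setA %in% universe) || !all(setB %in% universe))
        stop("both sets must be subsets of the universe")
    obs <- length(intersect(setA, setB))
    inB <- universe %in% setB
    nU <- length(universe)
    nA <- length(setA)
    set.seed(seed)
    null <- vapply(seq_len(nPerm),
                   function(i) sum(inB[sample.int(nU, nA)]), numeric(1))
    k <- if (alternative == "greater") sum(null >= obs) else sum(null <= obs)
    list(overlap = obs, expected = mean(null),
         fold = obs / mean(null),
         report = PermutationReport("set overlap", obs, nPerm, k, seed))
}
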