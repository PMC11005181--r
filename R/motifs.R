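#' Filter motif entries by origin-gene expression and assign origin class
#'
#' Keeps motifs whose cognate TF gene is expressed (log2 RPKM > `minGe` in
#' at least one lineage). Entries whose origin gene is missing from the
#' expression table are dropped and logged. When a classification is
#' supplied, each retained motif is annotated with the origin class of its
#' TF gene (DEG_<lineage>, SEG or other).
#'
#' @param entries motif data.frame (see [readMotifList()]).
#' @param expr log2 RPKM matrix (genes x ect/end/mes).
#' @param classes optional result of [classifyGenes()].
#' @param minGe expression floor (default 0).
#' @return the retained entries with an `origin_class` column.
#' @export
filterByExpression <- function(entries, expr, classes = NULL, minGe = 0) {
    expr <- .checkExpr(expr)
    resolved <- entries$origin_gene %in% rownames(expr)
    if (any(!resolved))
        message("filterByExpression: dropped ", sum(!resolved),
                " motifs with unresolvable origin genes")
    entries <- entries[resolved, , drop = FALSE]
    e <- expr[entries$origin_gene, , drop = FALSE]
    e[is.na(e)] <- -Inf
    keep <- apply(e, 1L, max) > minGe
    entries <- entries[keep, , drop = FALSE]
    cls <- rep("other", nrow(entries))
    if (!is.null(classes)) {
        lab <- classes$class_label[match(entries$origin_gene,
                                         classes$gene_id)]
        cls[startsWith(lab %|NA|% "", "DEG")] <- lab[startsWith(
            lab %|NA|% "", "DEG")]
        cls[(lab %|NA|% "") == "SEG"] <- "SEG"
    }
    entries$origin_class <- cls
    entries
}

#' Union of motif names across lists
#' @param lists list of motif data.frames.
#' @return sorted character vector of distinct motif names.
#' @export
motifUnion <- function(lists) sort(unique(unlist(lapply(lists,
                                                        `[[`, "motif"))))

# quartile of rank r in a list of n: boundaries at ceiling(n/4),
# ceiling(n/2), ceiling(3n/4) -- a 5-motif list splits (2,1,1,1)
.quartileOfRank <- function(r, n) {
    1L + (r > ceiling(n / 4)) + (r > ceiling(n / 2)) +
        (r > ceiling(3 * n / 4))
}

#' Quartile-rank feature vector of one motif list over the shared union
#'
#' Motifs are ordered by enrichment score (descending; ties by name for
#' determinism) and assigned their frequency quartile: 1 for the top
#' quarter of the list through 4 for the bottom quarter. Motifs of the
#' union absent from the list score 0. Ranks are invariant under any
#' strictly increasing transformation of the scores.
#'
#' @param entries motif data.frame with `motif` and `score`.
#' @param union character vector of the shared motif union (fixed across
#'   all compared sets).
#' @return named integer vector over `union` with entries in 0..4.
#' @export
buildRepertoireVector <- function(entries, union) {
    if (anyDuplicated(entries$motif))
        stop("duplicated motif within one list")
    if (!all(entries$motif %in% union))
        stop("list contains motifs outside the union")
    o <- order(-entries$score, entries$motif)
    n <- nrow(entries)
    q <- integer(n)
    q[o] <- .quartileOfRank(seq_len(n), n)
    v <- stats::setNames(integer(length(union)), union)
    v[entries$motif] <- q
    v
}

#' RMSE dissimilarity between two repertoire vectors
#'
#' sqrt(mean((v1 - v2)^2)) over the full shared union (absent motifs count
#' as 0): the RMSE of fitting the paired feature scores to the identity
#' line y = x. Higher RMSE means less similar repertoires. This is a
#' metric on vectors (up to the 1/sqrt(n) scaling of the Euclidean
#' distance).
#'
#' @param v1,v2 equal-length numeric vectors over the same union.
#' @return numeric scalar >= 0.
#' @examples
#' rmseSimilarity(c(1, 1, 1, 1), c(3, 3, 3, 3))  # 2
#' rmseSimilarity(c(1, 0), c(0, 2))              # sqrt(5/2)
#' @export
rmseSimilarity <- function(v1, v2) {
    if (length(v1) != length(v2))
        stop("vectors must share the same union length")
    sqrt(mean((v1 - v2)^2))
}

#' Within- and between-group repertoire similarity
#'
#' Computes all pairwise RMSEs between repertoire vectors and summarises
#' them as median RMSE within and between the groups (e.g. DEG-enhancer,
#' DEG-promoter, SEG-enhancer, SEG-promoter), plus a two-sample t-test of
#' the within vs between pairwise values.
#'
#' @param vectors numeric matrix, union x sets (columns are repertoire
#'   vectors), or a list coercible to one.
#' @param groups factor/character of length ncol(vectors) assigning each
#'   set to a group.
#' @return list with `pairwise` (full RMSE matrix), `medianTable`
#'   (group x group median pairwise RMSE), `within`, `between` (the raw
#'   pairwise values) and `tTest`.
#' @export
groupSimilarity <- function(vectors, groups) {
    vectors <- .asVectorMatrix(vectors)
    groups <- as.character(groups)
    stopifnot(length(groups) == ncol(vectors))
    ns <- ncol(vectors)
    pw <- matrix(0, ns, ns, dimnames = list(colnames(vectors),
                                            colnames(vectors)))
    for (i in seq_len(ns)) for (j in seq_len(ns))
        pw[i, j] <- rmseSimilarity(vectors[, i], vectors[, j])
    gl <- unique(groups)
    med <- matrix(NA_real_, length(gl), length(gl),
                  dimnames = list(gl, gl))
    within <- numeric()
    between <- numeric()
    for (a in seq_along(gl)) for (b in seq_len(a)) {
        ia <- which(groups == gl[a])
        ib <- which(groups == gl[b])
        vals <- if (a == b) {
            if (length(ia) < 2L) numeric() else
                pw[ia, ia][upper.tri(pw[ia, ia])]
        } else as.vector(pw[ia, ib, drop = FALSE])
        med[a, b] <- med[b, a] <- if (length(vals)) stats::median(vals)
                                  else NA_real_
        if (a == b) within <- c(within, vals) else between <- c(between,
                                                                vals)
    }
    tt <- if (length(within) >= 2L && length(between) >= 2L &&
              (stats::sd(within) > 0 || stats::sd(between) > 0))
        stats::t.test(between, within) else NULL
    list(pairwise = pw, medianTable = med, within = within,
         between = between, tTest = tt)
}

.asVectorMatrix <- function(vectors) {
    if (is.list(vectors) && !is.matrix(vectors))
        vectors <- do.call(cbind, vectors)
    as.matrix(vectors)
}

#' GC-stratified rank permutation test for repertoire structure
#'
#' Tests whether the within-group vs between-group similarity gap could
#' arise from repertoires assembled at random from motifs of the same
#' GC composition. Motifs of the union are stratified into quartiles of
#' consensus GC content; each null draw independently permutes every
#' repertoire vector's entries (rank and presence together) within each
#' stratum, preserving each list's rank multiset and GC profile. The
#' statistic is median(between) - median(within) pairwise RMSE. With
#' singleton strata the permutation is the identity and p = 1.
#'
#' @param vectors union x sets matrix of repertoire vectors.
#' @param gc numeric vector of per-motif GC content aligned with the union
#'   rows.
#' @param groups group assignment of the columns.
#' @param nPerm,seed permutation count and RNG seed.
#' @param nStrata number of GC strata (default 4, quartiles).
#' @return A [PermutationReport-class] on the similarity gap.
#' @export
gcStratifiedPermutation <- function(vectors, gc, groups, nPerm = 1000,
                                    seed = 1, nStrata = 4) {
    vectors <- .asVectorMatrix(vectors)
    stopifnot(length(gc) == nrow(vectors))
    br <- unique(stats::quantile(gc, probs = seq(0, 1,
                                                 length.out = nStrata + 1)))
    strata <- if (length(br) > 2L)
        cut(gc, br, include.lowest = TRUE, labels = FALSE)
    else rep(1L, length(gc))
    strataIdx <- split(seq_along(gc), strata)
    # all pairwise RMSEs at once: squared distances from the Gram matrix
    groups <- as.character(groups)
    ns <- ncol(vectors)
    sameGroup <- outer(groups, groups, "==")
    upper <- upper.tri(sameGroup)
    gap <- function(m) {
        g <- crossprod(m)
        d2 <- outer(diag(g), diag(g), "+") - 2 * g
        pw <- sqrt(pmax(d2, 0) / nrow(m))
        stats::median(pw[upper & !sameGroup]) -
            stats::median(pw[upper & sameGroup])
    }
    obs <- gap(vectors)
    set.seed(seed)
    null <- vapply(seq_len(nPerm), function(i) {
        m <- vectors
        for (idx in strataIdx) {
            if (length(idx) < 2L) next
            for (j in seq_len(ncol(m)))
                m[idx, j] <- m[sample(idx), j]
        }
        gap(m)
    }, numeric(1))
    PermutationReport("within/between similarity gap", obs, nPerm,
                      sum(null >= obs), seed)
}

# fractional nucleotide composition of one consensus, resolving IUPAC
# degenerate symbols (R contributes 1/2 A + 1/2 G, N contributes 1/4 each)
.consensusProfile <- function(consensus) {
    sym <- strsplit(toupper(consensus), "")[[1]]
    map <- Biostrings::IUPAC_CODE_MAP
    bad <- setdiff(sym, names(map))
    if (length(bad))
        stop("unknown consensus symbol: ", paste(unique(bad),
                                                 collapse = ", "))
    t(vapply(sym, function(s) {
        bases <- strsplit(map[[s]], "")[[1]]
        p <- c(A = 0, C = 0, G = 0, T = 0)
        p[bases] <- 1 / length(bases)
        p
    }, numeric(4)))
}

#' Sequence features of motif consensi
#'
#' Single-nucleotide content Px = count(x) / length, dinucleotide content
#' Pxy = count(xy) / (length - 1) and the dinucleotide entropy
#' -sum Pxy log2(Pxy) (bits), a complexity measure: 0 for homopolymers, up
#' to log2 of the number of distinct adjacent pairs. IUPAC degenerate
#' symbols contribute fractional counts.
#'
#' @param entries motif data.frame with `motif` and `consensus` (consensus
#'   length >= 2 for dinucleotide features).
#' @return `DataFrame` with `motif`, `length`, `Pa`, `Pc`, `Pg`, `Pt`,
#'   `gc` and `entropy`.
#' @examples
#' motifFeatures(data.frame(motif = c("m1", "m2"),
#'                          consensus = c("AAAA", "ACGT")))$entropy
#' @export
motifFeatures <- function(entries) {
    feats <- lapply(entries$consensus, function(cs) {
        prof <- .consensusProfile(cs)
        L <- nrow(prof)
        px <- colMeans(prof)
        ent <- NA_real_
        if (L >= 2L) {
            pxy <- matrix(0, 4, 4)
            for (i in seq_len(L - 1L))
                pxy <- pxy + outer(prof[i, ], prof[i + 1L, ])
            pxy <- pxy / (L - 1L)
            nz <- pxy[pxy > 0]
            ent <- -sum(nz * log2(nz))
        }
        c(length = L, px, gc = unname(px["C"] + px["G"]), entropy = ent)
    })
    m <- do.call(rbind, feats)
    DataFrame(motif = entries$motif, length = as.integer(m[, "length"]),
              Pa = m[, "A"], Pc = m[, "C"], Pg = m[, "G"], Pt = m[, "T"],
              gc = m[, "gc"], entropy = m[, "entropy"])
}

#' GC content of consensus sequences (fractional for IUPAC symbols)
#' @param consensus character vector of consensus sequences.
#' @return numeric vector of GC fractions.
#' @export
consensusGC <- function(consensus)
    vapply(consensus, function(cs) {
        px <- colMeans(.consensusProfile(cs))
        unname(px["C"] + px["G"])
    }, numeric(1), USE.NAMES = FALSE)

#' Compare motif sequence features between groups
#'
#' Nonparametric comparison of entropy (complexity), A-content and length
#' between motif groups: Mann-Whitney for two groups, Kruskal-Wallis for
#' more.
#'
#' @param features `DataFrame` from [motifFeatures()].
#' @param groups group assignment aligned with the feature rows.
#' @return named list of htest objects (entropy, a_content, length).
#' @export
compareMotifFeatures <- function(features, groups) {
    groups <- factor(groups)
    one <- function(v) {
        if (nlevels(groups) == 2L)
            stats::wilcox.test(split(v, groups)[[1]],
                               split(v, groups)[[2]], exact = FALSE)
        else stats::kruskal.test(v, groups)
    }
    list(entropy = one(features$entropy), a_content = one(features$Pa),
         length = one(as.numeric(features$length)))
}
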