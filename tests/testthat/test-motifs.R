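test_that("expression filter drops silent origins and classes the rest", {
    entries <- data.frame(motif = c("m1", "m2", "m3", "m4"),
                          score = c(9, 8, 7, 6),
                          consensus = c("ACGT", "GGCC", "TTAA", "CGCG"),
                          origin_gene = c("tfA", "tfB", "tfC", "ghost"))
    ge <- exprFromLinear(c(0.3, 0.3, 0.3),   # all log2 < 0: dropped
                         c(10, 10, 10), c(9, 1, 1),
                         ids = c("tfA", "tfB", "tfC"))
    cl <- classifyGenes(ge)
    res <- suppressMessages(filterByExpression(entries, ge, cl))
    expect_identical(res$motif, c("m2", "m3"))
    expect_identical(res$origin_class, c("SEG", "DEG_ectoderm"))
})

test_that("quartile ranks follow the ceiling rule and score invariance", {
    u <- sprintf("m%02d", 1:10)
    four <- data.frame(motif = u[1:4], score = c(9, 7, 5, 3))
    v4 <- buildRepertoireVector(four, u)
    expect_equal(unname(v4[u[1:4]]), 1:4)
    expect_equal(unname(v4[u[5:10]]), rep(0L, 6))
    five <- data.frame(motif = u[1:5], score = c(9, 8, 7, 6, 5))
    v5 <- buildRepertoireVector(five, u)
    expect_equal(unname(v5[u[1:5]]), c(1, 1, 2, 3, 4))  # sizes (2,1,1,1)
    # strictly monotone transformation of scores leaves ranks unchanged
    five2 <- transform(five, score = exp(score / 2) + 1)
    expect_identical(buildRepertoireVector(five2, u), v5)
    expect_error(buildRepertoireVector(
        data.frame(motif = c("m01", "m01"), score = c(1, 2)), u),
        "duplicated")
})

test_that("RMSE similarity closed forms and metric properties", {
    expect_equal(rmseSimilarity(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(rmseSimilarity(rep(1, 4), rep(3, 4)), 2)
    expect_equal(rmseSimilarity(c(1, 0), c(0, 2)), sqrt(5 / 2))
    expect_error(rmseSimilarity(1:3, 1:4), "union")
    set.seed(51)
    for (i in 1:50) {
        a <- sample(0:4, 12, TRUE); b <- sample(0:4, 12, TRUE)
        c <- sample(0:4, 12, TRUE)
        expect_equal(rmseSimilarity(a, b), rmseSimilarity(b, a))
        expect_lte(rmseSimilarity(a, c),
                   rmseSimilarity(a, b) + rmseSimilarity(b, c) + 1e-12)
        expect_equal(rmseSimilarity(a, a), 0)
    }
})

test_that("motif features: closed-form entropies and bounds", {
    f <- motifFeatures(data.frame(
        motif = c("homo", "acgt", "gaga", "iupac"),
        consensus = c("AAAA", "ACGT", "GAGA", "RRRR")))
    expect_equal(f$entropy[1], 0)
    expect_equal(f$Pa[1], 1)
    expect_equal(f$entropy[2], log2(3))
    expect_equal(f$entropy[3], -(2 / 3) * log2(2 / 3) -
                     (1 / 3) * log2(1 / 3))
    # R = A/G half-and-half: 4 equiprobable dinucleotides -> 2 bits
    expect_equal(f$entropy[4], 2)
    expect_equal(f$gc[4], 0.5)
    set.seed(52)
    cons <- vapply(1:40, function(i)
        paste(sample(c("A", "C", "G", "T"),
                     sample(6:12, 1), TRUE), collapse = ""), character(1))
    ff <- motifFeatures(data.frame(motif = seq_along(cons),
                                   consensus = cons))
    expect_true(all(ff$entropy >= 0 & ff$entropy <= 4))
    expect_true(all(abs(ff$Pa + ff$Pc + ff$Pg + ff$Pt - 1) < 1e-12))
    expect_error(motifFeatures(data.frame(motif = "x", consensus = "AXX")),
                 "unknown")
})

test_that("group similarity separates disjoint grammars", {
    u <- sprintf("m%02d", 1:20)
    mk <- function(sel) { v <- stats::setNames(rep(0L, 20), u)
        v[sel] <- rep(1:4, length.out = length(sel)); v }
    vecs <- cbind(a1 = mk(1:8), a2 = mk(1:8), b1 = mk(13:20),
                  b2 = mk(13:20))
    gs <- groupSimilarity(vecs, c("A", "A", "B", "B"))
    expect_equal(gs$medianTable["A", "A"], 0)
    expect_gt(gs$medianTable["A", "B"], 0)
    expect_gt(stats::median(gs$between), stats::median(gs$within))
    # all-identical vectors: every median 0
    same <- cbind(x = mk(1:5), y = mk(1:5), z = mk(1:5), w = mk(1:5))
    gs0 <- groupSimilarity(same, c("A", "A", "B", "B"))
    expect_true(all(gs0$medianTable == 0))
})

test_that("GC-stratified permutation: identity strata, calibration, power", {
    u <- sprintf("m%02d", 1:8)
    vecs <- cbind(a = 1:8, b = 8:1, c = rep(2, 8), d = rep(3, 8))
    # one motif per stratum: permutation is the identity and p = 1
    res1 <- gcStratifiedPermutation(vecs, gc = (1:8) / 10,
                                    groups = c("A", "A", "B", "B"),
                                    nPerm = 50, seed = 1, nStrata = 8)
    expect_equal(pValue(res1), 1)
    # planted structure (shared within-grammar cores) survives
    # stratification under uniform GC
    lists <- generateMotifLists(nMotifs = 40, withinOverlap = 0.8,
                                betweenOverlap = 0.2, gcSplit = 0.5,
                                fracSilent = 0, seed = 3)
    u2 <- motifUnion(lists)
    vecs2 <- vapply(lists, buildRepertoireVector, integer(length(u2)),
                    union = u2)
    gc2 <- consensusGC(vapply(u2, function(m) {
        for (l in lists) if (m %in% l$motif)
            return(l$consensus[match(m, l$motif)])
    }, character(1)))
    groups <- c(rep("DEG_enh", 3), rep("DEG_cp", 3), "SEG_enh", "SEG_cp")
    res2 <- gcStratifiedPermutation(vecs2, gc2, groups, nPerm = 200,
                                    seed = 4)
    expect_lt(pValue(res2), 0.05)
})

test_that("generated motif lists respect overlap and GC controls", {
    # full within-grammar overlap: identical membership; with equalised
    # scores the repertoire vectors coincide and RMSE is 0
    full <- generateMotifLists(nMotifs = 20, withinOverlap = 1,
                               betweenOverlap = 0, seed = 5)
    expect_setequal(full$enh_ect$motif, full$cp_ect$motif)
    u <- motifUnion(full["enh_ect"])
    eq <- function(l) { l$score <- seq(10, 1, length.out = nrow(l)); l }
    expect_equal(rmseSimilarity(
        buildRepertoireVector(eq(full$enh_ect), u),
        buildRepertoireVector(eq(full$cp_ect), u)), 0)
    # zero overlap everywhere: disjoint support
    disj <- generateMotifLists(nMotifs = 10, withinOverlap = 0,
                               betweenOverlap = 0, seed = 6)
    expect_length(intersect(disj$enh_ect$motif, disj$enh_end$motif), 0)
    expect_length(intersect(disj$enh_ect$motif, disj$enh_seg$motif), 0)
    # gcSplit drives SEG consensi GC-rich
    gcl <- generateMotifLists(nMotifs = 50, gcSplit = 0.9, seed = 7)
    expect_gt(mean(consensusGC(gcl$enh_seg$consensus)),
              mean(consensusGC(gcl$enh_ect$consensus)))
    expect_error(generateMotifLists(withinOverlap = 0.1,
                                    betweenOverlap = 0.9), "infeasible")
})
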