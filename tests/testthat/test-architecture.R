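test_that("nearest-expressed distances: adjacency, filtering, oracle", {
    genes <- makeGenes("chr1", c(100, 1000, 5000), ids = c("a", "b", "c"))
    geAll <- exprFromLinear(c(8, 8, 8), c(8, 8, 8), c(8, 8, 8),
                            ids = c("a", "b", "c"))
    d <- nearestExpressedDistance(genes, geAll, threshold = 0)
    expect_equal(d$d[d$gene_id == "b"], 900)
    # filtering the middle gene makes the flanks mutual neighbours
    geMid <- geAll
    geMid["b", ] <- log2(c(0.5, 0.5, 0.5))  # below threshold 0
    d2 <- nearestExpressedDistance(genes, geMid, threshold = 0)
    expect_false("b" %in% d2$gene_id)
    expect_equal(d2$d, c(4900, 4900))

    set.seed(21)
    tss <- sort(sample.int(2e6, 50))
    chrom <- rep("chr1", 50)
    g <- makeGenes(chrom, tss)
    dAll <- nearestExpressedDistance(g)
    expect_equal(dAll$d, oracleNearest(chrom, tss))
})

test_that("nearest-distance symmetry and threshold monotonicity hold", {
    set.seed(22)
    tss <- sort(sample.int(5e5, 40))
    g <- makeGenes("chr1", tss)
    ge <- matrix(stats::rnorm(120, 1, 2), ncol = 3,
                 dimnames = list(g$gene_id, c("ect", "end", "mes")))
    d0 <- nearestExpressedDistance(g, ge, threshold = -3)
    # symmetry: my nearest neighbour's own distance is no larger than mine
    pos <- stats::setNames(d0$tss, d0$gene_id)
    for (i in seq_len(nrow(d0))) {
        nb <- d0$gene_id[which(abs(pos - pos[i]) == d0$d[i] &
                                   names(pos) != d0$gene_id[i])]
        expect_true(any(d0$d[d0$gene_id %in% nb] <= d0$d[i]))
    }
    # monotonicity across the configured threshold ladder
    prev <- d0
    for (th in c(-2, -1, 0, 1, 2, 3)) {
        cur <- nearestExpressedDistance(g, ge, threshold = th)
        shared <- intersect(cur$gene_id, prev$gene_id)
        expect_true(all(cur$d[match(shared, cur$gene_id)] >=
                            prev$d[match(shared, prev$gene_id)],
                        na.rm = TRUE))
        prev <- cur
    }
})

test_that("distance comparison behaves at the extremes and on planted gaps", {
    x <- c(1, 2, 3, 4, 5)
    expect_gt(compareDistances(x, x)$p.value, 0.9)
    set.seed(3)
    degD <- stats::rexp(200, 1 / 100000)
    segD <- stats::rexp(200, 1 / 10000)
    cmp <- compareDistances(degD, segD)
    expect_lt(cmp$p.value, 0.01)
    expect_gt(cmp$medians["deg"], cmp$medians["seg"])
    # single-element samples take the exact small-sample route
    expect_equal(compareDistances(1, 2)$p.value, 1)
    expect_warning(cmp0 <- compareDistances(c(5, 5), c(5, 5)), "tied")
    expect_equal(cmp0$p.value, 1)
})

test_that("TAD summaries: density arithmetic, containment oracle, conservation", {
    tads <- makeTads("chr1", c(0, 500000), c(500000, 600000))
    genes <- makeGenes("chr1", c(1e4, 1e5, 2e5, 3e5, 4e5),
                       class_label = c("DEG_ectoderm", "SEG", "SEG",
                                       "unclassified", "DEG_mesoderm"))
    ts <- tadSummaries(tads, genes)
    expect_equal(ts$density, c(5 * 1e5 / 5e5, 0))
    expect_equal(ts$n_DEG, c(2, 0))
    expect_identical(ts$content, c("mixed", "empty"))

    set.seed(31)
    tstart <- seq(0, 9e5, by = 1e5)
    tads2 <- makeTads("chr1", tstart, tstart + 80000)
    tss <- sample.int(1e6, 50)
    genes2 <- makeGenes("chr1", tss)
    ts2 <- tadSummaries(tads2, genes2)
    expect_equal(ts2$n_genes,
                 oracleTadCounts(tstart, tstart + 80000,
                                 rep("chr1", 10), tss, rep("chr1", 50)))
    expect_equal(sum(ts2$n_genes), 50 - metadata(ts2)$n_unassigned)
    # boundary: TSS exactly at a TAD end belongs to the next interval
    gb <- makeGenes("chr1", c(80000, 100000))
    tb <- tadSummaries(tads2, gb)
    expect_equal(tb$n_genes[1], 0)
    expect_equal(tb$n_genes[2], 1)
})

test_that("TAD co-occurrence test detects planted segregation", {
    tads <- makeTads("chr1", seq(0, 9e5, 1e5), seq(0, 9e5, 1e5) + 9e4)
    # DEGs in the first five TADs, SEGs in the last five: no mixed TAD
    tss <- c(seq(0, 4e5, 1e5) + 1e4, seq(0, 4e5, 1e5) + 5e4,
             seq(5e5, 9e5, 1e5) + 1e4, seq(5e5, 9e5, 1e5) + 5e4)
    genes <- makeGenes("chr1", tss)
    deg <- genes$gene_id[1:10]
    seg <- genes$gene_id[11:20]
    res <- tadCooccurrenceTest(tads, genes, deg, seg, nPerm = 500, seed = 1)
    expect_equal(res$nMixed, 0)
    expect_lt(pValue(res$report), 0.05)
    # one TAD holding everything: the null cannot move the statistic
    one <- makeTads("chr1", 0, 1e6)
    res1 <- tadCooccurrenceTest(one, genes, deg, seg, nPerm = 100, seed = 1)
    expect_equal(pValue(res1$report), 1)
})

test_that("CG-rich promoter calls and the class association test", {
    seqs <- c(g1 = strrep("GC", 150), g2 = strrep("AT", 150),
              g3 = paste0(strrep("CG", 80), strrep("A", 140)))
    genes <- makeGenes("chr1", c(1, 2, 3) * 1000, ids = names(seqs),
                       class_label = c("SEG", "DEG_ectoderm", "SEG"))
    res <- cgRichPromoter(genes, sequences = seqs)
    expect_true(res$perGene$cg_rich[1])
    expect_false(res$perGene$cg_rich[2])
    expect_identical(dim(res$table), c(2L, 2L))
    # the exact one-tailed test on a 72/100 vs 45/100 split, against the
    # hypergeometric closed form
    stats <- data.frame(gene_id = sprintf("p%03d", 1:200),
                        gc = c(rep(0.6, 72), rep(0.3, 28),
                               rep(0.6, 45), rep(0.3, 55)),
                        cpg_oe = 0.7, width = 1500)
    genes2 <- makeGenes("chr1", seq_len(200) * 1000, ids = stats$gene_id,
                        class_label = rep(c("SEG", "DEG_ectoderm"),
                                          each = 100))
    res2 <- cgRichPromoter(genes2, promoterStats = stats)
    expect_equal(res2$fisher$p.value,
                 8.686975434e-05, tolerance = 1e-8)
    expect_lt(res2$fisher$p.value, 0.001)
})
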