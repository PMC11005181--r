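test_that("accessibility-index profile normalisation and oracle equality", {
    # one focal gene, one region in one bin, one expressed gene in vicinity
    focal <- makeGenes("chr1", 50000)
    reg <- GRanges("chr1", IRanges(57001, width = 100))  # centre +7050
    prof <- accessibilityIndexProfile(reg, focal, focal, V = 20000,
                                      bin = 5000)
    expect_equal(sum(prof$index), 1)
    expect_equal(prof$index[prof$bin_start == 5000], 1)
    # an extra focal gene with an empty vicinity halves every bin
    focal2 <- makeGenes("chr1", c(50000, 500000))
    expressed2 <- makeGenes("chr1", c(50000, 480000))
    prof2 <- accessibilityIndexProfile(reg, focal2, expressed2, V = 20000,
                                       bin = 5000)
    expect_equal(prof2$index[prof2$bin_start == 5000], 0.5)
    expect_error(accessibilityIndexProfile(reg, focal, focal, V = 1000,
                                           bin = 5000), "bin")

    set.seed(41)
    tss <- sort(sample.int(3e6, 50))
    genes <- makeGenes("chr1", tss,
                       strand = sample(c("+", "-"), 50, replace = TRUE))
    regs <- GRanges("chr1", IRanges(sort(sample.int(3e6, 300)),
                                    width = 100))
    V <- 50000; bin <- 5000
    prof3 <- accessibilityIndexProfile(regs, genes, genes, V, bin)
    sgn <- ifelse(as.character(strand(genes)) == "-", -1, 1)
    expect_equal(prof3$index,
                 oracleProfile((start(regs) + floor(width(regs) / 2)), start(genes),
                               start(genes), V, bin, sgn))
})

test_that("CAC: perfect proportionality, degeneracy, invariances", {
    # three genes whose region counts are exactly proportional to GE
    tss <- c(1e5, 5e5, 9e5)
    genes <- makeGenes("chr1", tss)
    ge <- c(3, 6, 9)
    regs <- GRanges("chr1", IRanges(
        unlist(mapply(function(t, k) t + seq_len(k) * 200, tss,
                      c(1, 2, 3))), width = 100))
    cc <- cacScore(genes, ge, regs, genes, V = 10000)
    expect_equal(cc$r, 1)
    expect_equal(cc$nPoints, 3)
    # constant frequency across genes is degenerate and flagged
    regsConst <- GRanges("chr1", IRanges(tss + 500, width = 100))
    ccc <- cacScore(genes, ge, regsConst, genes, V = 10000)
    expect_true(is.na(ccc$r))
    # permuting gene order and rescaling GE leave r unchanged
    set.seed(42)
    tss2 <- sort(sample.int(5e6, 80))
    genes2 <- makeGenes("chr1", tss2)
    ge2 <- stats::runif(80, 2, 6)
    regs2 <- GRanges("chr1", IRanges(sort(sample.int(5e6, 600)),
                                     width = 100))
    r0 <- cacScore(genes2, ge2, regs2, genes2, V = 50000)$r
    o <- sample(80)
    expect_equal(cacScore(genes2[o], ge2[o], regs2, genes2, V = 50000)$r,
                 r0)
    expect_equal(cacScore(genes2, ge2 * 3, regs2, genes2, V = 50000)$r, r0)
})

test_that("zone scan recovers the planted scale and flags null inputs", {
    sc <- simulateLinkingScenario(seed = 4)
    zs <- zoneScan(sc$tss, sc$ge, sc$regions, sc$tss,
                   grid = c(20, 40, 80, 120, 160, 200, 300, 400) * 1000)
    expect_s4_class(zs, "ZoneScan")
    expect_gte(max(cacCurve(zs)$r, na.rm = TRUE), 0.7)
    expect_true(zStar(zs) >= 1e5 / 1.5 && zStar(zs) <= 1.5 * 1e5)
    # regions independent of genes: among grid points with enough
    # frequency groups for a stable estimate, no meaningful association
    set.seed(44)
    nullRegs <- GRanges("chr1", IRanges(sort(sample.int(5e7, 3000)),
                                        width = 100))
    zn <- zoneScan(sc$tss, sc$ge, nullRegs, sc$tss)
    el <- as.data.frame(cacCurve(zn))
    el <- el[el$eligible, ]
    expect_gt(nrow(el), 0)
    expect_lt(max(abs(el$r)), 0.5)
    expect_gt(min(el$p), 0.05)
    # a single grid value is its own argmax
    z1 <- zoneScan(sc$tss, sc$ge, sc$regions, sc$tss, grid = 80000)
    expect_equal(zStar(z1), 80000)
    expect_error(zoneScan(sc$tss, sc$ge, sc$regions, sc$tss,
                          grid = c(2e4, 1e4)), "increasing")
})

test_that("linking respects the radius and never crosses TAD boundaries", {
    tads <- makeTads("chr1", 0, 200000)
    genes <- makeGenes("chr1", 100000, ids = "g1")
    dar <- GRanges("chr1", IRanges(149951, width = 100))  # centre 150,000
    lk <- linkRegions(genes, dar, tads, zStar = 80000)
    expect_equal(length(lk), 1)
    expect_equal(lk$distance, 50000)
    # same distances, but a boundary at 120 kB separates the pair
    tads2 <- makeTads("chr1", c(0, 120000), c(120000, 300000))
    expect_equal(length(linkRegions(genes, dar, tads2, 80000)), 0)
    # beyond the radius
    far <- GRanges("chr1", IRanges(184951, width = 100))  # centre 185,000
    expect_equal(length(linkRegions(genes, far, tads, 80000)), 0)
    # negative-strand genes get negative downstream distances
    gm <- makeGenes("chr1", 100000, strand = "-", ids = "g1")
    expect_equal(linkRegions(gm, dar, tads, 80000)$distance, -50000)
    expect_error(linkRegions(genes, dar, NULL, 80000), "TAD")
})

test_that("link catalogue equals the brute-force double loop", {
    set.seed(45)
    tstart <- seq(0, 1.8e6, by = 2e5)
    tads <- makeTads("chr1", tstart, tstart + 150000)
    tss <- sort(sample.int(2e6, 50))
    genes <- makeGenes("chr1", tss,
                       strand = sample(c("+", "-"), 50, replace = TRUE))
    regs <- GRanges("chr1", IRanges(sort(sample.int(2e6, 200)),
                                    width = 100))
    lk <- linkRegions(genes, regs, tads, zStar = 60000)
    or <- oracleLinks(genes, regs, tads, 60000)
    expect_equal(length(lk), nrow(or))
    ok <- order(start(lk), lk$gene_id)
    expect_identical(lk$gene_id[ok], or$gene)
    expect_equal(start(lk)[ok], or$region_start)
    expect_equal(lk$distance[ok], or$distance)
    sm <- linkSummary(lk)
    expect_equal(sm$n_links, length(lk))
    expect_true(sm$frac_beyond >= 0 && sm$frac_beyond <= 1)
})

test_that("peak association reproduces the region-based scan", {
    sc <- simulateLinkingScenario(nGenes = 150, chromLength = 2.5e7,
                                  seed = 6)
    grid <- c(40, 80, 160) * 1000
    za <- zoneScan(sc$tss, sc$ge, sc$regions, sc$tss, grid = grid)
    zb <- peakAssociation(sc$tss, sc$ge, sc$regions, sc$tss, grid = grid)
    expect_equal(cacCurve(za)$r, cacCurve(zb)$r)
    expect_error(peakAssociation(sc$tss, sc$ge, GRanges(), sc$tss),
                 "empty")
})
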