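test_that("window levels are the direct count ratio", {
    sw <- SignalWindows(GRanges("chr1", IRanges(c(1, 101, 201), width = 100)),
                        reads = matrix(30, 3, 3),
                        dinucTotal = rbind(c(10, 10, 10), c(8, 8, 8),
                                           c(10, 0, 10)),
                        dinucMeth = rbind(c(5, 0, 10), c(4, 4, 4),
                                          c(1, 0, 1)))
    expect_message(lw <- windowLevels(sw), "dropped 1")
    expect_equal(nrow(lw), 2)
    expect_equal(unname(assay(lw, "level")[1, ]), c(0.5, 0, 1))
    set.seed(8)
    tot <- matrix(stats::rpois(60, 20) + 1, 20, 3)
    met <- matrix(stats::rbinom(60, as.vector(tot), 0.4), 20, 3)
    sw2 <- SignalWindows(GRanges("chr1", IRanges(1:20 * 200, width = 100)),
                         matrix(30, 20, 3), tot, met)
    expect_equal(unname(assay(windowLevels(sw2), "level")),
                 unname(met / tot))
})

test_that("QC coverage filter and the two balance variants", {
    sw <- SignalWindows(
        GRanges("chr1", IRanges(c(1, 201, 401, 601), width = 100)),
        reads = rbind(c(30, 30, 30), c(20, 30, 30), c(200, 30, 30),
                      c(60, 50, 40)),
        dinucTotal = matrix(10, 4, 3), dinucMeth = matrix(5, 4, 3))
    cv <- suppressMessages(qcFilter(sw, "cv"))
    # balanced passes; (20,30,30) fails the >25-read rule; (200,30,30)
    # fails the coverage-balance cv; moderate spread passes
    expect_equal(start(rowRanges(cv$windows)), c(1, 601))
    expect_true(cv$report$n_pass_coverage >= cv$report$n_pass_gc_balance)
    lit <- suppressMessages(qcFilter(sw, "literal"))
    # the printed inequality |max|d_ij| - mean| < sd rejects the perfectly
    # balanced window (|0 - 30| < 0 is false)
    expect_false(1 %in% start(rowRanges(lit$windows)))
    expect_error(qcFilter(SignalWindows(
        GRanges("chr1", IRanges(1, width = 100)),
        matrix(-1, 1, 3), matrix(1, 1, 3), matrix(0, 1, 3))),
        "non-negative|negative")
})

test_that("accessibility calls split DAR / SAR_HA / SAR_LA correctly", {
    sw <- windowsFromLevels(c(0.60, 0.20, 0.20,
                              0.40, 0.39, 0.39,
                              0.10, 0.10, 0.10,
                              0.50, 0.45, 0.45), denom = 100)
    regs <- callAccessibilityRegions(sw)
    # window 4 has Da = 0.357: neither DAR nor SAR
    expect_equal(length(regs), 3)
    expect_identical(regs$region_class, c("DAR", "SAR_HA", "SAR_LA"))
    expect_identical(regs$lineage, c("ect", "all", "all"))
    expect_equal(regs$dominance[2], 0.40 / 1.18, tolerance = 1e-6)
    # DAR and SAR sets are disjoint by construction
    expect_false(any(duplicated(start(regs))))
})

test_that("methylation calls honour polarity and the ShMR ceiling", {
    sw <- windowsFromLevels(c(0.1, 0.9, 0.9,
                              0.1, 0.1, 0.1,
                              0.8, 0.8, 0.8), width = 500, denom = 1000)
    hy <- callMethylationRegions(sw, "hypo")
    expect_identical(hy$region_class, c("DhMR", "ShMR"))
    expect_identical(hy$lineage[1], "ect")      # most hypomethylated
    expect_equal(hy$dominance[1], 0.9 / 1.1, tolerance = 1e-6)
    # evenly but highly methylated window is not a ShMR
    expect_false(any(hy$region_class == "ShMR" & hy$mean_level > 0.5))
    lit <- callMethylationRegions(sw, "literal")
    # on M itself the (0.1,0.9,0.9) window is not dominant (0.9/1.9 < 0.6)
    expect_false(any(start(lit) == start(sw)[1] &
                         lit$region_class == "DhMR"))
})

test_that("cluster fraction: exact placement, cross-chromosome, Poisson law", {
    a <- GRanges("chr1", IRanges(c(1e4, 5e4, 9e4), width = 100))
    res <- clusterFraction(a, a, vicinity = 1000, nPerm = 50, seed = 1)
    expect_equal(res$fraction, 1)
    expect_equal(res$jaccard, 1)
    b <- GRanges("chr2", IRanges(1e4, width = 100))
    expect_equal(suppressWarnings(
        clusterFraction(a, b, nPerm = 20, seed = 1)$fraction), 0)
    # uniform A and B at density rho: P(>= 1 B centre within +/-v) is
    # approximately 1 - exp(-2 v rho)
    set.seed(12)
    len <- 2e6
    a2 <- GRanges("chr1", IRanges(sort(sample.int(len, 400)), width = 100))
    b2 <- GRanges("chr1", IRanges(sort(sample.int(len, 100)), width = 100))
    res2 <- clusterFraction(a2, b2, vicinity = 10000, nPerm = 20, seed = 2,
                            chromLengths = c(chr1 = len))
    expect_equal(res2$fraction, 1 - exp(-2 * 10000 * 100 / len),
                 tolerance = 0.08)
})

test_that("cv QC accepts balance and rejects strong coverage imbalance", {
    set.seed(13)
    lam <- 50
    balanced <- matrix(stats::rpois(300, lam), 100, 3)
    skew <- cbind(stats::rpois(100, 6 * lam), stats::rpois(100, lam / 2),
                  stats::rpois(100, lam / 2))
    sw <- SignalWindows(GRanges("chr1", IRanges(1:200 * 200, width = 100)),
                        rbind(balanced, skew), matrix(12, 200, 3),
                        matrix(5, 200, 3))
    res <- suppressMessages(qcFilter(sw, "cv"))
    kept <- start(rowRanges(res$windows))
    expect_gt(mean((1:100 * 200) %in% kept), 0.95)
    expect_lt(mean((101:200 * 200) %in% kept), 0.05)
})

test_that("planted DARs are recalled from generated windows", {
    ds <- generateDataset(simulationSpec(seed = 5))
    lw <- suppressMessages(windowLevels(ds$accWindows))
    qc <- suppressMessages(qcFilter(lw))
    regs <- suppressMessages(callAccessibilityRegions(qc$windows))
    dars <- regs[regs$region_class == "DAR"]
    truth <- ds$truth$regions[ds$truth$regions$class == "DAR"]
    hit <- GenomicRanges::countOverlaps(truth, dars, type = "equal") > 0
    expect_gte(mean(hit), 0.9)
    # called lineage matches the planted lineage
    ov <- GenomicRanges::findOverlaps(truth, dars, type = "equal")
    expect_gt(mean(truth$lineage[S4Vectors::queryHits(ov)] ==
                       dars$lineage[S4Vectors::subjectHits(ov)]), 0.99)
})
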