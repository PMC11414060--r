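mkTrack <- function(pos, counts, id, strand = "+") {
    g <- GRanges("chr1", IRanges(pos, width = 1), strand = strand)
    g$count <- as.integer(counts)
    truncationTrack(g, id)
}

test_that("site counting sums the flanked window per sample", {
    site <- GRanges("chr1", IRanges(100, width = 1), strand = "+")
    tr <- mkTrack(c(98, 100, 103), c(2, 7, 5), "s1")
    ## flank 0: only the site position
    m0 <- countSites(site, list(s1 = tr), flank = 0)
    expect_identical(unname(SummarizedExperiment::assay(m0)[1, 1]), 7L)
    ## flank 2: 98..102
    m2 <- countSites(site, list(s1 = tr), flank = 2)
    expect_identical(unname(SummarizedExperiment::assay(m2)[1, 1]), 9L)
    ## identical samples get identical size factors
    m <- countSites(site, list(a = tr, b = tr))
    expect_identical(unname(sizeFactors(m)["a"]),
                     unname(sizeFactors(m)["b"]))
})

test_that("median-of-ratios recovers a known scaling factor", {
    set.seed(21)
    pos <- seq(10, 10 + 30 * 7, by = 7)
    base <- rpois(length(pos), 50) + 1L
    t1 <- mkTrack(pos, base, "s1")
    t2 <- mkTrack(pos, base * 2L, "s2")
    sites <- GRanges("chr1", IRanges(pos, width = 1), strand = "+")
    m <- countSites(sites, list(s1 = t1, s2 = t2), flank = 0)
    sf <- sizeFactors(m)
    expect_equal(unname(sf["s2"] / sf["s1"]), 2, tolerance = 1e-12)
    ## normalization invariance: normalized matrices agree across scalings
    expect_equal(normalizedCounts(m)[, "s1"], normalizedCounts(m)[, "s2"],
                 tolerance = 1e-12)
})

test_that("two-group comparison matches an exhaustive Mann-Whitney oracle", {
    set.seed(5)
    for (trial in 1:10) {
        x <- round(rnorm(7, 10, 3), 2)
        y <- round(rnorm(8, 12, 3), 2)
        cmp <- compareGroups(c(x, y),
                             factor(rep(c("a", "b"), c(7, 8)),
                                    levels = c("a", "b")))
        orc <- oracleMannWhitney(x, y)
        expect_identical(unname(cmp@statistic), orc$U)
        ## normal approximation with continuity correction vs exact
        ## enumeration: close for these group sizes
        expect_lt(abs(cmp@pValue - orc$p), 0.035)
    }
})

test_that("group comparisons behave under null, shift, and three groups", {
    set.seed(9)
    a <- rnorm(200)
    cmpNull <- compareGroups(c(a, a), factor(rep(c("g1", "g2"), each = 200)))
    expect_gt(cmpNull@pValue, 0.9)     # identical groups
    expect_equal(unname(diff(cmpNull@groupMeans)), 0)
    cmpShift <- compareGroups(c(a, a + 5),
                              factor(rep(c("g1", "g2"), each = 200)))
    expect_lt(cmpShift@pValue, 1e-10)
    ## three groups, one shifted: Tukey flags exactly the two contrasts
    ## involving the shifted group
    b <- rnorm(60)
    vals <- c(b, b, b + 3)
    g <- factor(rep(c("x", "y", "z"), each = 60))
    cmp3 <- compareGroups(vals, g)
    expect_identical(cmp3@method, "anova_tukey")
    sig <- cmp3@pairwise$p_adj < 0.01
    names(sig) <- cmp3@pairwise$contrast
    expect_identical(unname(sig[c("y-x", "z-x", "z-y")]),
                     c(FALSE, TRUE, TRUE))
    expect_error(compareGroups(a, factor(rep("one", 200))), "two groups")
})

test_that("normalized count comparisons flow through a count matrix", {
    ## a uniform scaling of one sample is pure depth and must be absorbed
    ## by its size factor; a drop at a subset of sites must be detected
    set.seed(33)
    pos <- seq(10, 10 + 60 * 9, by = 9)
    base <- rpois(length(pos), 40) + 1L
    dropSites <- seq_len(20)            # 20 of 61 sites lose signal in kd
    kdCounts <- base
    kdCounts[dropSites] <- pmax(1L, as.integer(round(base[dropSites] / 5)))
    tracks <- list(
        c1 = mkTrack(pos, base, "c1"),
        c2 = mkTrack(pos, base * 2L, "c2"),     # deeper, same composition
        k1 = mkTrack(pos, kdCounts, "k1"),
        k2 = mkTrack(pos, kdCounts * 2L, "k2"))
    sites <- GRanges("chr1", IRanges(pos, width = 1), strand = "+")
    m <- countSites(sites, tracks, flank = 0)
    ## depth is absorbed: factors of the doubled samples are twice those of
    ## their partners
    sf <- sizeFactors(m)
    expect_equal(unname(sf["c2"] / sf["c1"]), 2, tolerance = 1e-12)
    cmp <- compareGroups(m, factor(c("ctrl", "ctrl", "kd", "kd"),
                                   levels = c("ctrl", "kd")))
    expect_lt(cmp@pValue, 1e-3)
})

test_that("ddct reproduces the closed form exactly and inverts", {
    ## ddCT 0, 1, -2 -> RQ 1, 0.5, 4
    expect_identical(ddct(21, 11, 20, 10), 1)
    expect_identical(ddct(22, 11, 20, 10), 0.5)
    expect_identical(ddct(19, 11, 20, 10), 4)
    set.seed(2)
    ct <- matrix(runif(40, 10, 30), ncol = 4)
    rq <- ddct(ct[, 1], ct[, 2], ct[, 3], ct[, 4])
    expect_equal(-log2(rq),
                 (ct[, 1] - ct[, 2]) - (ct[, 3] - ct[, 4]),
                 tolerance = 1e-12)
    expect_error(ddct(NA, 1, 1, 1), "is.finite")
})

test_that("target vs non-target fold-change comparison detects a shift", {
    sim <- cachedSim()
    fc <- simulateGeneFoldchanges(sim, effect = 0.3, nGenes = 2000,
                                  seed = 61)
    v <- structure(fc$log2fc, names = fc$gene_id)
    cmp <- targetVsNontargetFoldchange(v, fc$gene_id[fc$is_target])
    expect_lt(cmp@pValue, 1e-4)
    expect_lt(cmp@groupMeans["target"], cmp@groupMeans["non_target"])
    ## effect 0: distributions identical in expectation, p not extreme
    fc0 <- simulateGeneFoldchanges(sim, effect = 0, nGenes = 2000,
                                   seed = 62)
    v0 <- structure(fc0$log2fc, names = fc0$gene_id)
    cmp0 <- targetVsNontargetFoldchange(v0, fc0$gene_id[fc0$is_target])
    expect_gt(cmp0@pValue, 0.001)
    ## degenerate partitions are errors
    expect_error(targetVsNontargetFoldchange(v, fc$gene_id), "non-target")
    expect_error(targetVsNontargetFoldchange(v, "absent_gene"),
                 "no overlap")
})
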