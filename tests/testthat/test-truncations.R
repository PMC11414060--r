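test_that("truncation positions follow the iCLIP convention", {
    r <- GRanges(rep("chr1", 3), IRanges(c(101, 101, 1), c(135, 135, 35)),
                 strand = c("+", "-", "+"))
    tr <- extractTruncations(r, "s1")
    s <- truncationSites(tr)
    ## + read [101,135] -> 100; - read [101,135] -> 136; read at origin
    ## would truncate at 0 and is dropped with a counter
    expect_setequal(start(s), c(100L, 136L))
    expect_identical(unname(tr@dropped["negative_coordinate"]), 1L)
    expect_identical(librarySize(tr), 2)
    ## unstranded records are skipped and counted
    r2 <- GRanges("chr1", IRanges(50, 60), strand = "*")
    tr2 <- extractTruncations(r2, "s2")
    expect_identical(librarySize(tr2), 0)
    expect_identical(unname(tr2@dropped["unstranded"]), 1L)
    ## empty input
    tr3 <- extractTruncations(GRanges(), "s3")
    expect_identical(librarySize(tr3), 0)
})

test_that("event conservation: library size equals usable reads", {
    n <- 500
    pos <- sample2(100:5000, n, seed = 3)
    r <- GRanges("chr1", IRanges(pos, pos + 34),
                 strand = sample2(c("+", "-"), n, seed = 4))
    tr <- extractTruncations(r, "s")
    expect_identical(librarySize(tr), as.numeric(n))
    expect_identical(sum(truncationSites(tr)$count), as.integer(n))
})

test_that("binomial CITS p-values match a summation oracle", {
    ## one transcript spanning 1000 nt, n = 100 truncations, one position
    ## carries k = 10
    genome <- DNAStringSet(c(chr1 = strrep("ACGT", 300)))
    exons <- GRangesList(t1 = GRanges("chr1", IRanges(1, 1000),
                                      strand = "+"))
    idx <- buildAnnotationIndex(exons, GRangesList(), c(t1 = "g1"), genome)
    bgPos <- sample2(1:1000, 90, seed = 8, replace = FALSE)
    bgPos <- setdiff(bgPos, 500)[1:89]
    sites <- GRanges("chr1", IRanges(c(500, bgPos), width = 1),
                     strand = "+")
    sites$count <- c(10L, rep(1L, 89))
    track <- truncationTrack(sites, "s")
    expect_identical(librarySize(track), 10 + 89)
    peaks <- callCits(track, idx, citsParams())
    expect_length(peaks, 1L)
    expect_identical(start(peaks), 500L)
    expect_equal(peaks$p_value, oracleBinomTail(10, 99, 1 / 1000),
                 tolerance = 1e-12)
    expect_lte(peaks$q_value, 0.01)
    ## uniform k = 1 everywhere: nothing reaches minCount, no peaks
    u <- sites; u$count <- rep(1L, length(u))
    expect_length(callCits(truncationTrack(u, "u"), idx), 0L)
})

test_that("increasing k at a position never increases its p-value", {
    p <- vapply(2:30, function(k)
        pbinom(k - 1, 200, 1 / 1500, lower.tail = FALSE), numeric(1))
    expect_true(all(diff(p) < 0))
})

test_that("control filtering equals a set-difference oracle", {
    mk <- function(pos, strand = "+")
        GRanges("chr1", IRanges(pos, width = 1), strand = strand)
    ## stated examples
    out <- filterAgainstControl(mk(c(100, 200)), mk(200))
    expect_identical(start(out), 100L)
    expect_length(filterAgainstControl(mk(c(100, 200)), mk(c(100, 200))), 0L)
    expect_length(filterAgainstControl(mk(c(100, 200)), GRanges()), 2L)
    ## randomized agreement with a plain set difference
    for (trial in 1:20) {
        a <- unique(sample2(1:500, 80, seed = 100 + trial))
        b <- unique(sample2(1:500, 80, seed = 200 + trial))
        got <- filterAgainstControl(mk(a), mk(b))
        expect_setequal(start(got), setdiff(a, b))
    }
    ## strandedness: a minus-strand control does not mask a plus peak
    expect_length(filterAgainstControl(mk(100), mk(100, "-")), 1L)
})

test_that("replicate merging follows the gap rule and a clustering oracle", {
    mk <- function(pos, k = 1, strand = "+") {
        g <- GRanges("chr1", IRanges(pos, width = 1), strand = strand)
        g$k <- k
        g
    }
    ## identical sites at gap 0 collapse to one
    m <- mergeReplicatePeaks(list(mk(100), mk(100)), gap = 0)
    expect_identical(start(m), 100L)
    expect_identical(m$k, 2)
    ## positions 100 and 102 merge at gap 1 (one intervening base)
    m <- mergeReplicatePeaks(list(mk(100, 5), mk(102, 3)), gap = 1)
    expect_length(m, 1L)
    expect_identical(start(m), 100L)      # highest summed k wins
    ## 100 and 103 exceed the gap
    expect_length(mergeReplicatePeaks(list(mk(100), mk(103)), gap = 1), 2L)
    ## gap 0 collapses identical positions only
    expect_length(mergeReplicatePeaks(list(mk(100), mk(101)), gap = 0), 2L)
    ## tie on summed k resolves 5'-most in transcript sense
    m <- mergeReplicatePeaks(list(mk(c(100, 102), c(2, 2))), gap = 1)
    expect_identical(start(m), 100L)
    m <- mergeReplicatePeaks(list(mk(c(100, 102), c(2, 2), "-")), gap = 1)
    expect_identical(start(m), 102L)
    ## randomized equivalence with single-linkage clustering, plus
    ## idempotence and order-invariance
    for (trial in 1:30) {
        gap <- trial %% 3
        a <- unique(sample2(1:300, 40, seed = 300 + trial))
        b <- unique(sample2(1:300, 40, seed = 400 + trial))
        got <- mergeReplicatePeaks(list(mk(a), mk(b)), gap = gap)
        maxDiff <- if (gap == 0) 0 else gap + 1
        cl <- oracleClusters(c(a, b), maxDiff)
        expect_identical(length(got), length(cl))
        ## every reported position is a member of its cluster
        for (i in seq_along(got))
            expect_true(any(vapply(cl, function(x)
                start(got)[i] %in% x, logical(1))))
        swapped <- mergeReplicatePeaks(list(mk(b), mk(a)), gap = gap)
        expect_identical(start(got), start(swapped))
        again <- mergeReplicatePeaks(list(got), gap = gap)
        expect_identical(start(again), start(got))
    }
})

test_that("input normalization forms CPM ratios per bin", {
    s <- GRanges("chr1", IRanges(c(10, 75, 160), width = 1), strand = "+")
    s$count <- c(10L, 20L, 40L)
    clip <- truncationTrack(s, "clip")
    smi <- truncationTrack(s, "smi")
    ## identical tracks give ratio exactly 1 in every occupied bin
    r <- normalizeToInput(clip, smi, binSize = 50)
    expect_equal(r$ratio, rep(1, length(r)))
    ## CPM is depth-normalized, so a uniform doubling cancels; local
    ## enrichment shows up as the CPM ratio in the limit eps -> 0
    s3 <- s; s3$count <- c(40L, 20L, 40L)
    r3 <- normalizeToInput(truncationTrack(s3, "c3"), smi, binSize = 50,
                           pseudocount = 1e-9)
    cpmC <- c(40, 20, 40) / 100 * 1e6
    cpmS <- c(10, 20, 40) / 70 * 1e6
    expect_equal(r3$ratio, cpmC / cpmS, tolerance = 1e-6)
    expect_error(normalizeToInput(clip, truncationTrack(GRanges(), "e")),
                 "un-normalized")
})
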