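## single-exon coding transcripts with region lengths that are exact
## multiples of the bin counts, so uniform events give exactly flat bins
binExactIndex <- function(scales = c(1L, 2L)) {
    u5 <- 50L; cd <- 100L; u3 <- 70L
    txs <- lapply(scales, function(s) c(u5, cd, u3) * s)
    total <- vapply(txs, sum, integer(1))
    starts <- cumsum(c(101L, total[-length(total)] + 500L))
    genome <- DNAStringSet(c(chr1 = strrep("ACGT",
                                           ceiling((max(starts + total) +
                                                    500) / 4))))
    exons <- GRangesList(lapply(seq_along(txs), function(i)
        GRanges("chr1", IRanges(starts[i], starts[i] + total[i] - 1L),
                strand = "+")))
    names(exons) <- paste0("tx", seq_along(txs))
    cds <- GRangesList(lapply(seq_along(txs), function(i)
        GRanges("chr1", IRanges(starts[i] + txs[[i]][1],
                                starts[i] + txs[[i]][1] + txs[[i]][2] - 1L),
                strand = "+")))
    names(cds) <- names(exons)
    gids <- structure(paste0("g", seq_along(txs)), names = names(exons))
    list(index = buildAnnotationIndex(exons, cds, gids, genome),
         starts = starts, dims = txs)
}

test_that("events at CDS start collapse to a single spike after scaling", {
    fx <- binExactIndex(c(1L, 2L, 3L))
    cdsStarts <- fx$starts + vapply(fx$dims, `[`, integer(1), 1L)
    ev <- GRanges("chr1", IRanges(cdsStarts, width = 1), strand = "+")
    ev$count <- c(5L, 7L, 3L)
    prof <- metageneProfile(ev, fx$index)
    tab <- metageneTable(prof)
    hot <- tab$density > 0
    expect_identical(sum(hot), 1L)
    expect_identical(tab$region[hot], "cds")
    expect_identical(tab$bin_index[hot], 0L)
})

test_that("uniform events give a flat profile and CPM scale invariance", {
    fx <- binExactIndex(c(1L, 2L))
    ev <- do.call(c, lapply(seq_along(fx$starts), function(i)
        GRanges("chr1", IRanges(seq(fx$starts[i],
                                    fx$starts[i] + sum(fx$dims[[i]]) - 1L),
                                width = 1), strand = "+")))
    ev$count <- rep(1L, length(ev))
    prof <- metageneProfile(ev, fx$index)
    d <- prof@density
    ## flat within each region (exact, since bins tile regions evenly)
    for (r in c("utr5", "cds", "utr3")) {
        dr <- d[prof@bins$region == r]
        expect_equal(max(dr) - min(dr), 0, tolerance = 1e-12)
    }
    ## conservation of profiled events
    expect_identical(prof@nEvents, as.numeric(length(ev)))
    ## multiplying every count by 10 leaves the CPM profile unchanged
    ev10 <- ev; ev10$count <- ev$count * 10L
    expect_equal(metageneProfile(ev10, fx$index)@density, d,
                 tolerance = 1e-12)
})

test_that("profiles are invariant to transcript length rescaling", {
    ## two transcripts, the second a doubled copy with stretched events:
    ## per-bin averaged CPM must agree with the single-transcript profile
    fx1 <- binExactIndex(1L)
    fx2 <- binExactIndex(c(1L, 2L))
    mkEvents <- function(fx) {
        ## spikes at proportional mRNA offsets: 20% into the 5'UTR, 10%
        ## into the CDS, 50% into the 3'UTR of every transcript
        do.call(c, lapply(seq_along(fx$starts), function(i) {
            dims <- fx$dims[[i]]
            off <- c(round(0.2 * dims[1]),
                     dims[1] + round(0.1 * dims[2]),
                     dims[1] + dims[2] + round(0.5 * dims[3]))
            g <- GRanges("chr1", IRanges(fx$starts[i] + off, width = 1),
                         strand = "+")
            g$count <- c(4L, 2L, 6L)
            g
        }))
    }
    p1 <- metageneProfile(mkEvents(fx1), fx1$index)
    p2 <- metageneProfile(mkEvents(fx2), fx2$index)
    ## densities differ by the library-size factor only; shapes identical
    shape <- function(p) p@density / sum(p@density)
    expect_equal(shape(p2), shape(p1), tolerance = 1e-12)
})

test_that("feature distribution reports raw percent and per-Kb rates", {
    fx <- binExactIndex(1L)            # utr5 50, cds 100, utr3 70 nt
    u5pos <- seq(fx$starts[1], fx$starts[1] + 9L)
    peaks <- GRanges("chr1", IRanges(u5pos, width = 1), strand = "+")
    fd <- featureDistribution(peaks, fx$index)
    expect_identical(fd$count[fd$region == "utr5"], 10L)
    expect_equal(fd$percent[fd$region == "utr5"], 100)
    expect_equal(fd$peaks_per_kb[fd$region == "utr5"], 10 / 0.050)
    ## per-Kb identity holds exactly for every region
    ok <- fd$length_kb > 0
    expect_equal(fd$peaks_per_kb[ok] * fd$length_kb[ok], fd$count[ok])
    ## a peak outside every transcript is bucketed intergenic
    far <- GRanges("chr1", IRanges(5, 5), strand = "+")
    fd2 <- featureDistribution(far, fx$index)
    expect_identical(attr(fd2, "intergenic"), 1L)
    expect_identical(sum(fd2$count), 0L)
})

test_that("region assignment agrees with a brute-force scan on real-ish data", {
    sim <- cachedSim()
    idx <- annotationIndex(sim)
    set.seed(31)
    lens <- structure(Biostrings::width(sim@genome),
                      names = names(sim@genome))
    n <- 400
    chs <- sample(names(lens), n, replace = TRUE)
    pos <- vapply(chs, function(ch) sample.int(lens[ch], 1), numeric(1))
    peaks <- GRanges(chs, IRanges(as.integer(pos), width = 1),
                     strand = sample(c("+", "-"), n, replace = TRUE))
    fd <- featureDistribution(peaks, idx)
    ## brute force: longest-mRNA transcript whose span covers the peak,
    ## then linear scan of its feature intervals
    td <- idx@txdata
    bruteRegion <- vapply(seq_len(n), function(i) {
        cand <- which(td$chrom == as.character(seqnames(peaks))[i] &
                      td$strand == as.character(strand(peaks))[i] &
                      td$span_start <= start(peaks)[i] &
                      td$span_end >= start(peaks)[i])
        if (!length(cand)) return("intergenic")
        cand <- cand[order(-td$mrna_length[cand],
                           td$transcript_id[cand])][1]
        f <- txFeatures(idx, td$transcript_id[cand])
        hit <- which(start(f) <= start(peaks)[i] &
                     end(f) >= start(peaks)[i])
        r <- f$region[hit]
        if (r == "exon") "noncoding" else r
    }, character(1))
    for (r in fd$region)
        expect_identical(fd$count[fd$region == r], sum(bruteRegion == r))
    expect_identical(attr(fd, "intergenic"), sum(bruteRegion == "intergenic"))
})
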